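# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards so library code never clobbers user randomness.
# seed = NULL draws from the current stream (still restartable by the caller).
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# derive a reproducible child seed from a parent seed, bounded to R's int range
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 48271 + as.integer(k)) %% 2147483587L
}

abort_domain <- function(msg, class = "mutualstab_domain_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_fraction <- function(x, name, open_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 &&
    (if (open_upper) x < 1 else x <= 1)
  if (!ok) abort_domain(sprintf("`%s` must be a fraction in [0, 1%s", name,
                                if (open_upper) ")" else "]"))
  invisible(x)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort_domain(sprintf("`%s` must be a positive number", name))
  }
  invisible(x)
}
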