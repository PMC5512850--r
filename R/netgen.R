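#' Sample a bipartite network from target degree sequences
#'
#' Draws each link `(i, k)` independently with probability
#' `min(1, f * deg_P[i] * deg_A[k] / L)`, where `L = sum(deg_P) = sum(deg_A)`.
#' At `f = 1` the expected degree of every species equals its target degree, so
#' the expected connectance equals the connectance of the template network; `f`
#' scales the connectance up or down while keeping the degree-distribution
#' shape. Networks with an unconnected species are rejected and redrawn.
#'
#' @param deg_P,deg_A Non-negative integer degree sequences for plants and
#'   animals with equal sums.
#' @param f Positive connectance multiplier.
#' @param seed Optional integer seed (fixed seed gives a bit-identical draw).
#' @param max_retries Cap on empty-species repair rounds.
#' @return A [bipartite_network()].
#' @export
sample_network <- function(deg_P, deg_A, f = 1, seed = NULL, max_retries = 100L) {
  if (!isTRUE(all.equal(sum(deg_P), sum(deg_A))) || sum(deg_P) <= 0) {
    abort_domain("degree sequences must have equal, positive sums")
  }
  assert_positive(f, "f")
  L <- sum(deg_P)
  p <- f * outer(as.numeric(deg_P), as.numeric(deg_A)) / L
  p[p > 1] <- 1
  local_seed(seed, {
    inc <- matrix(stats::rbinom(length(p), 1L, as.vector(p)),
                  nrow = length(deg_P))
    # empty-species policy: species with target degree >= 1 must end up with a
    # link; redraw only the empty rows/columns (low-degree species are empty
    # with probability ~exp(-d), so whole-matrix rejection cannot work at
    # sparse connectance)
    for (try in seq_len(max_retries)) {
      er <- which(rowSums(inc) == 0L)
      for (i in er) inc[i, ] <- stats::rbinom(ncol(inc), 1L, p[i, ])
      ec <- which(colSums(inc) == 0L)
      for (k in ec) inc[, k] <- stats::rbinom(nrow(inc), 1L, p[, k])
      if (all(rowSums(inc) > 0L) && all(colSums(inc) > 0L)) {
        return(bipartite_network(inc))
      }
    }
    abort_domain(
      sprintf("empty species remain after %d repair rounds (f too small?)",
              max_retries),
      class = "mutualstab_generation_error")
  })
}

#' Uniform random bipartite network at fixed expected connectance
#'
#' Erdos-Renyi-style null model: every link present independently with
#' probability `kappa`. Used as the reference ensemble for [rho_crit_zscore()].
#'
#' @inheritParams sample_network
#' @param S_P,S_A Numbers of plant and animal species.
#' @param kappa Link probability (expected connectance).
#' @export
random_bipartite <- function(S_P, S_A, kappa, seed = NULL, max_retries = 100L) {
  assert_fraction(kappa, "kappa")
  local_seed(seed, {
    inc <- matrix(stats::rbinom(S_P * S_A, 1L, kappa), nrow = S_P)
    for (try in seq_len(max_retries)) {
      er <- which(rowSums(inc) == 0L)
      for (i in er) inc[i, ] <- stats::rbinom(S_A, 1L, kappa)
      ec <- which(colSums(inc) == 0L)
      for (k in ec) inc[, k] <- stats::rbinom(S_P, 1L, kappa)
      if (all(rowSums(inc) > 0L) && all(colSums(inc) > 0L)) {
        return(bipartite_network(inc))
      }
    }
    abort_domain(
      sprintf("empty species remain after %d repair rounds (kappa too small?)",
              max_retries),
      class = "mutualstab_generation_error")
  })
}

#' Reference degree sequences at field-study scale
#'
#' Deterministic, broadly distributed (truncated power-law-like) degree
#' sequences for a community of `S_P` plants and `S_A` animals with `L` links,
#' emulating the heterogeneous degrees of empirical pollinator webs. Defaults
#' give 47 plants x 46 animals at connectance ~0.07, the scale at which the
#' simulation ensembles in this package are run.
#'
#' @param S_P,S_A Guild sizes.
#' @param L Total number of links.
#' @param exponent Decay exponent of the rank-degree profile.
#' @return List with integer vectors `deg_P`, `deg_A` (each summing to `L`,
#'   minimum degree 1).
#' @export
study_degrees <- function(S_P = 47, S_A = 46, L = 151, exponent = 0.9) {
  make_seq <- function(S) {
    if (L < S) abort_domain("need at least one link per species")
    shape <- seq_len(S)^(-exponent)
    d <- pmax(1L, round(L * shape / sum(shape)))
    # repair rounding drift on the high-degree end, keeping every degree >= 1
    i <- 1L
    while (sum(d) != L) {
      step <- sign(L - sum(d))
      if (d[i] + step >= 1L) d[i] <- d[i] + as.integer(step)
      i <- i %% S + 1L
    }
    as.integer(d)
  }
  list(deg_P = make_seq(S_P), deg_A = make_seq(S_A))
}

#' Tune network nestedness by degree-preserving checkerboard swaps
#'
#' Rewires a bipartite network towards a target (pooled) nestedness while
#' keeping both degree sequences exactly fixed. An elementary move picks two
#' links `(i1,k1)`, `(i2,k2)` with `(i1,k2)` and `(i2,k1)` absent and exchanges
#' them (a checkerboard swap). A move is accepted whenever it reduces
#' `|nu - target_nu|`; otherwise it is accepted with Metropolis probability
#' `exp(-increase / temperature)`. The run stops when
#' `|nu - target_nu| <= tolerance` or after `max_swaps` valid proposals.
#'
#' @param net A [bipartite_network()].
#' @param target_nu Target pooled nestedness in `[0, 1]`.
#' @param max_swaps Cap on valid proposed moves.
#' @param tolerance Convergence half-width on `|nu - target_nu|`.
#' @param temperature Metropolis temperature (cost is `|nu - target|`).
#' @param seed Optional integer seed.
#' @return A `bipartite_network` with extra attributes: `swaps` (valid proposals
#'   used), `accepted`, `converged`, `nu` (final pooled nestedness). If no valid
#'   swap exists the input is returned with `converged = FALSE` and attribute
#'   `no_valid_swap = TRUE`.
#' @export
tune_nestedness <- function(net, target_nu, max_swaps = 30000L,
                            tolerance = 0.01, temperature = 1e-3,
                            seed = NULL) {
  net <- as_network(net)
  assert_fraction(target_nu, "target_nu")
  a <- net$incidence
  S_P <- nrow(a); S_A <- ncol(a)
  d_P <- rowSums(a); d_A <- colSums(a)

  # pair weights 1/min(d_i, d_j); degrees never change under swaps
  w_P <- 1 / outer(d_P, d_P, pmin); diag(w_P) <- 0
  w_A <- 1 / outer(d_A, d_A, pmin); diag(w_A) <- 0
  n_pairs <- S_P * (S_P - 1) / 2 + S_A * (S_A - 1) / 2

  num <- function() {
    cp <- tcrossprod(a) * w_P
    ca <- tcrossprod(t(a)) * w_A
    (sum(cp[upper.tri(cp)]) + sum(ca[upper.tri(ca)]))
  }
  nu_now <- num() / n_pairs

  finish <- function(swaps, accepted, converged, no_valid = FALSE) {
    out <- bipartite_network(a, plants = net$plants, animals = net$animals)
    attr(out, "swaps") <- swaps
    attr(out, "accepted") <- accepted
    attr(out, "converged") <- converged
    attr(out, "nu") <- nu_now
    if (no_valid) attr(out, "no_valid_swap") <- TRUE
    out
  }

  if (abs(nu_now - target_nu) <= tolerance) return(finish(0L, 0L, TRUE))
  reachable_hint <- if (target_nu > nu_now) "raise" else "lower"

  local_seed(seed, {
    links <- which(a == 1L, arr.ind = TRUE)
    swaps <- 0L; accepted <- 0L; misses <- 0L
    while (swaps < max_swaps) {
      pick <- sample.int(nrow(links), 2L)
      r1 <- links[pick[1L], 1L]; c1 <- links[pick[1L], 2L]
      r2 <- links[pick[2L], 1L]; c2 <- links[pick[2L], 2L]
      if (r1 == r2 || c1 == c2 || a[r1, c2] == 1L || a[r2, c1] == 1L) {
        misses <- misses + 1L
        if (misses > 5000L) {
          warning("no valid checkerboard swap found; returning input unchanged",
                  call. = FALSE)
          return(finish(swaps, accepted, FALSE, no_valid = TRUE))
        }
        next
      }
      misses <- 0L
      swaps <- swaps + 1L

      # incremental change of the pooled nestedness numerator
      dc <- a[, c2] - a[, c1]; dc[c(r1, r2)] <- 0
      dr <- a[r2, ] - a[r1, ]; dr[c(c1, c2)] <- 0
      d_num <- sum(dc * (w_P[r1, ] - w_P[r2, ])) +
        sum(dr * (w_A[c1, ] - w_A[c2, ]))
      nu_new <- nu_now + d_num / n_pairs

      d_cost <- abs(nu_new - target_nu) - abs(nu_now - target_nu)
      if (d_cost <= 0 || stats::runif(1) < exp(-d_cost / temperature)) {
        a[r1, c1] <- 0L; a[r2, c2] <- 0L; a[r1, c2] <- 1L; a[r2, c1] <- 1L
        links[pick[1L], ] <- c(r1, c2)
        links[pick[2L], ] <- c(r2, c1)
        nu_now <- nu_new
        accepted <- accepted + 1L
      }
      if (abs(nu_now - target_nu) <= tolerance) {
        return(finish(swaps, accepted, TRUE))
      }
    }
    warning(sprintf(
      "nestedness target %.3f not reached after %d swaps (nu = %.3f); target may be hard to %s at these degrees",
      target_nu, max_swaps, nu_now, reachable_hint), call. = FALSE)
    finish(swaps, accepted, FALSE)
  })
}
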