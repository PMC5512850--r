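# mean-field inverse of a competition matrix (1-rho) I + rho J
meanfield_inverse <- function(S, rho) {
  cc <- rho / (1 + (S - 1) * rho)
  (diag(S) - matrix(cc, S, S)) / (1 - rho)
}

# first-order critical competition for effective coupling structures
# Gamma_P (focal x other) and Gamma_A (other x focal): the focal guild's
# effective competition is beta_f - g^2 Gamma_P beta_o^{-1} Gamma_A, and the
# sign of the O(g^2) shift of rho_eff - rho flips at
#   rho_c = (S Q1 - T) / ((S - 1) T),
# with T the trace and Q1 the flat-vector quadratic form (mean row-sum) of
# X = Gamma_P beta_o^{-1} Gamma_A. The location of the flip does not depend
# on the overall coupling prefactor g; xi = g^2 T / S sets its magnitude via
# rho_eff = rho - xi (rho_c - rho).
closed_core <- function(Gamma_P, Gamma_A, rho_other, prefactor2) {
  S <- nrow(Gamma_P)
  Minv <- meanfield_inverse(ncol(Gamma_P), rho_other)
  X <- Gamma_P %*% Minv %*% Gamma_A
  Tt <- sum(diag(X))
  Q1 <- sum(X) / S
  list(rho_c = (S * Q1 - Tt) / ((S - 1) * Tt),
       xi = prefactor2 * Tt / S)
}

censor_label <- function(rho_c) {
  if (rho_c < 0) "below_zero" else if (rho_c > 1) "above_one" else "none"
}

#' Critical direct competition: regime closed forms
#'
#' First-order (in the mutualistic coupling) critical competition
#' \eqn{\rho^c} of the focal guild: the direct-competition level at which
#' mutualism switches from reducing to increasing the effective interspecific
#' competition, \eqn{\rho^{eff} = \rho - \xi(\rho^c - \rho)} with \eqn{\xi > 0}.
#'
#' Regimes differ only in the structure of the effective mutualistic
#' couplings entering the guild reduction:
#' * `"weak"` (all saturation factors small): couplings proportional to the
#'   incidence `a`; `xi = gamma0^2 T / S` is proportional to
#'   `kappa * S_other * gamma0^2`.
#' * `"strong"` (all saturation factors large): couplings proportional to
#'   `a / d^2` row-wise (each species' effective strengths shrink with the
#'   square of its weighted degree).
#' * `"weak_strong"` (obligatory: focal plants weak, animals strong): focal
#'   couplings `a`, other-side couplings `a / d^2`; the product is independent
#'   of `gamma0` and `xi = T / (S * h_A^2 * ratio_PA)` is tiny at realistic
#'   abundance ratios, so the deviation of `rho_eff` from `rho` is negligible.
#'
#' Fully connected networks give `rho_c = 1` exactly in the weak and strong
#' forms. Values outside `(0, 1)` are returned as is with a censoring label,
#' never clipped.
#'
#' @param net A [bipartite_network()] (or incidence matrix).
#' @param rho_other Direct competition of the non-focal guild.
#' @param gamma0 Mutualism scale (sets `xi`; `rho_c` is independent of it).
#' @param regime `"weak"`, `"strong"` or `"weak_strong"`.
#' @param focal `"plants"` or `"animals"`.
#' @param h_P,h_A Handling scales (used by the strong forms for `xi` and the
#'   validity warning).
#' @param ratio_PA Abundance-scale ratio (weak-strong `xi`).
#' @return List with `rho_c`, `xi`, `censored`, `regime`.
#' @export
rho_crit_closed_form <- function(net, rho_other, gamma0 = 0.1,
                                 regime = c("weak", "strong", "weak_strong"),
                                 focal = c("plants", "animals"),
                                 h_P = 1, h_A = 1, ratio_PA = 1e6) {
  regime <- match.arg(regime)
  focal <- match.arg(focal)
  net <- as_network(net)
  assert_fraction(rho_other, "rho_other", open_upper = TRUE)
  a <- net$incidence
  if (focal == "animals") a <- t(a)
  d_f <- rowSums(a); d_o <- colSums(a)
  h_f <- if (focal == "plants") h_P else h_A
  h_o <- if (focal == "plants") h_A else h_P

  weak_side_f <- a
  weak_side_o <- t(a)
  strong_side_f <- a / d_f^2
  strong_side_o <- t(a) / d_o^2

  core <- switch(regime,
    weak = {
      z_max <- h_f * gamma0 * max(d_f)
      if (z_max > 0.5) warning(sprintf(
        "weak closed form outside its validity range (max z ~ %.2f)", z_max),
        call. = FALSE)
      closed_core(weak_side_f, weak_side_o, rho_other, gamma0^2)
    },
    strong = {
      z_min <- min(h_f * gamma0 * min(d_f), h_o * gamma0 * min(d_o))
      if (z_min < 2) warning(sprintf(
        "strong closed form outside its validity range (min z ~ %.2f)", z_min),
        call. = FALSE)
      closed_core(strong_side_f, strong_side_o, rho_other,
                  1 / (h_f^2 * gamma0 * h_o^2 * gamma0))
    },
    weak_strong = closed_core(weak_side_f, strong_side_o, rho_other,
                              1 / (h_o^2 * ratio_PA))
  )
  list(rho_c = core$rho_c, xi = core$xi, censored = censor_label(core$rho_c),
       regime = regime)
}

#' Critical direct competition: numerical root of the full pipeline
#'
#' Regime-free numerical route: `rho_c` is the fixed point of the map
#' `rho -> rho_eff(rho)` computed by the full assembly-and-reduction pipeline
#' (deterministic coefficient draws, `delta_b = delta_c = delta_N = 0`), found
#' as the root of `g(rho) = rho_eff(rho) - rho` by bracketed bisection on a
#' scan grid. When `g` has no sign change on `(0, 1)` a censoring flag is
#' returned (`"below_zero"` when mutualism raises `rho_eff` everywhere,
#' `"above_one"` when it lowers it everywhere); multiple roots are all
#' returned with a warning.
#'
#' @param net A [bipartite_network()].
#' @param meta A [meta_parameters()] (its `rho` of the focal guild is swept;
#'   the delta widths are zeroed).
#' @param focal `"plants"` or `"animals"`.
#' @param tol Bisection tolerance on `rho`.
#' @param grid_n Number of scan points on `(0, 1)`.
#' @return List with `rho_c` (numeric vector, usually length 1; empty when
#'   censored), `censored`, and the scan tibble (`rho`, `rho_eff`).
#' @export
rho_crit_numeric <- function(net, meta = meta_parameters(), focal = "plants",
                             tol = 1e-6, grid_n = 21) {
  net <- as_network(net)
  m <- meta
  m$delta_b <- m$delta_c <- m$delta_N <- 0
  g <- function(rho) {
    if (focal == "plants") m$rho_P <- rho else m$rho_A <- rho
    comm <- build_community(net, m, seed = 1L, enforce_regime = FALSE)
    sys <- effective_system(comm)
    sys[[focal]]$rho_eff - rho
  }
  g_safe <- function(rho) {
    # strongly coupled systems can lose a positive effective diagonal at some
    # rho; such grid points are degenerate, not roots
    tryCatch(g(rho), error = function(e) NA_real_)
  }
  grid <- seq(0.01, 0.99, length.out = grid_n)
  gv <- vapply(grid, g_safe, numeric(1))
  scan <- tibble::tibble(rho = grid, rho_eff = gv + grid)
  if (all(is.na(gv))) {
    return(list(rho_c = numeric(0), censored = "degenerate", scan = scan))
  }
  flips <- which(diff(sign(gv)) != 0 & !is.na(gv[-length(gv)]) &
                   !is.na(gv[-1]))
  if (!length(flips)) {
    censored <- if (all(gv > 0, na.rm = TRUE)) "below_zero" else "above_one"
    return(list(rho_c = numeric(0), censored = censored, scan = scan))
  }
  roots <- vapply(flips, function(i) {
    stats::uniroot(g, c(grid[i], grid[i + 1]), tol = tol)$root
  }, numeric(1))
  if (length(roots) > 1) {
    warning(sprintf("%d roots of rho_eff(rho) = rho found", length(roots)),
            call. = FALSE)
  }
  list(rho_c = roots, censored = "none", scan = scan)
}

#' Critical direct competition: two-guild fixed point
#'
#' Alternates the per-guild closed forms — the plant critical competition
#' depends on the animal direct competition and vice versa — until the pair
#' `(rho_c_P, rho_c_A)` is a fixed point. Below this pair, mutualism reduces
#' the effective competition of both guilds. The iteration is damped by 0.5
#' when it oscillates; the fixed point is independent of the initial values.
#'
#' @param net A [bipartite_network()].
#' @param gamma0 Mutualism scale.
#' @param regime Closed-form regime, see [rho_crit_closed_form()].
#' @param init Initial `(rho_P, rho_A)`.
#' @param tol Convergence tolerance on successive change.
#' @param max_iter Iteration cap.
#' @param ... Passed to [rho_crit_closed_form()].
#' @return Tibble with `rho_c_P`, `rho_c_A`, `iterations`, `converged`,
#'   `censored_P`, `censored_A`; the iteration trace is in attribute
#'   `"trace"`.
#' @export
rho_crit_fixed_point <- function(net, gamma0 = 0.1, regime = "weak",
                                 init = c(0.5, 0.5), tol = 1e-8,
                                 max_iter = 1000, ...) {
  net <- as_network(net)
  clamp <- function(x) min(max(x, 1e-4), 1 - 1e-4)
  rp <- clamp(init[1]); ra <- clamp(init[2])
  raw_p <- rp; raw_a <- ra
  trace <- matrix(NA_real_, max_iter, 2)
  damp <- 1
  prev_step <- c(0, 0)
  for (it in seq_len(max_iter)) {
    # rho_c is independent of the coupling prefactor, so the closed form's
    # saturation-validity warning is irrelevant inside the iteration
    raw_p <- suppressWarnings(
      rho_crit_closed_form(net, rho_other = ra, gamma0 = gamma0,
                           regime = regime, focal = "plants", ...)$rho_c)
    new_p <- clamp(rp + damp * (clamp(raw_p) - rp))
    raw_a <- suppressWarnings(
      rho_crit_closed_form(net, rho_other = new_p, gamma0 = gamma0,
                           regime = regime, focal = "animals", ...)$rho_c)
    new_a <- clamp(ra + damp * (clamp(raw_a) - ra))
    step <- c(new_p - rp, new_a - ra)
    if (it > 1 && any(sign(step) * sign(prev_step) < 0)) damp <- 0.5
    prev_step <- step
    trace[it, ] <- c(new_p, new_a)
    delta <- max(abs(step))
    rp <- new_p; ra <- new_a
    if (delta < tol) {
      out <- tibble::tibble(rho_c_P = raw_p, rho_c_A = raw_a,
                            iterations = it, converged = TRUE,
                            censored_P = censor_label(raw_p),
                            censored_A = censor_label(raw_a))
      attr(out, "trace") <- trace[seq_len(it), , drop = FALSE]
      return(out)
    }
  }
  abort_domain(sprintf("fixed-point iteration did not converge in %d iterations",
                       max_iter))
}

#' Z-score of the critical competition against random networks
#'
#' Compares the plant-side fixed-point critical competition of a network with
#' a null ensemble of uniform-random bipartite networks with the same guild
#' sizes and the same expected connectance (links independent, no degree
#' constraint). Positive Z means the network's architecture lowers the
#' effective competition more than chance.
#'
#' @param net A [bipartite_network()].
#' @param n_null Null-ensemble size.
#' @param seed Integer seed.
#' @param gamma0,regime Passed to [rho_crit_fixed_point()].
#' @return Tibble with `rho_c` (observed, plant side), `null_mean`, `null_sd`,
#'   `z` (NA with a warning when the null spread vanishes), `n_null`.
#' @export
rho_crit_zscore <- function(net, n_null = 100, seed = NULL, gamma0 = 0.1,
                            regime = "weak") {
  net <- as_network(net)
  obs <- rho_crit_fixed_point(net, gamma0 = gamma0, regime = regime)$rho_c_P
  kappa <- connectance(net)
  null_vals <- vapply(seq_len(n_null), function(i) {
    nn <- random_bipartite(n_plants(net), n_animals(net), kappa,
                          seed = child_seed(seed, i))
    rho_crit_fixed_point(nn, gamma0 = gamma0, regime = regime)$rho_c_P
  }, numeric(1))
  m <- mean(null_vals); s <- stats::sd(null_vals)
  z <- if (s > 0) (obs - m) / s else {
    warning("null ensemble has zero spread; Z undefined", call. = FALSE)
    NA_real_
  }
  tibble::tibble(rho_c = obs, null_mean = m, null_sd = s, z = z,
                 n_null = n_null)
}
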