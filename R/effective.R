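#' Effective interspecific competition of a competition matrix
#'
#' With `lambda1` the leading eigenvalue of the (diagonal-normalized) effective
#' competition matrix and `lambda_minor` the mean of the remaining eigenvalues,
#' `(tr C - lambda1)/(S - 1)`, the effective interspecific-to-intraspecific
#' ratio is
#' \deqn{\rho^{eff} = \frac{\lambda_1 - \bar\lambda_m}{\lambda_1 + (S-1)\bar\lambda_m},}
#' the exact inversion of the mean-field spectrum: for
#' `C = (1-rho) I + rho J` it returns `rho` for any `S` and any `rho`.
#' When `diag(C) = 1` this reduces to `(lambda1 - 1)/(S - 1)`.
#'
#' @param C Square effective competition matrix (diagonal-normalized).
#' @return Scalar `rho_eff` (< 1; can be negative for facilitation-dominated
#'   spectra).
#' @export
rho_eff <- function(C) {
  S <- nrow(C)
  if (is.null(S) || S < 2) abort_domain("rho_eff needs at least 2 species")
  lambda1 <- max(Re(eigen(C, only.values = TRUE)$values))
  lambda_minor <- (sum(diag(C)) - lambda1) / (S - 1)
  (lambda1 - lambda_minor) / (lambda1 + (S - 1) * lambda_minor)
}

#' Feasibility threshold of the vulnerability
#'
#' `eta_crit = S_eff / (S_eff + S)` with `S_eff = (1 - rho_eff)/rho_eff` the
#' biodiversity scale set by the effective competition. As `rho_eff` tends to 0
#' the threshold tends to 1 (any productivity vector with positive components
#' is feasible); as `rho_eff` tends to 1 or `S` grows it tends to 0 (the
#' productivity vector must align with the leading eigenvector).
#'
#' @param rho_eff Effective interspecific competition in (0, 1).
#' @param S Number of species in the guild.
#' @export
eta_crit <- function(rho_eff, S) {
  out <- ifelse(rho_eff <= 0, 1,
                (1 - rho_eff) / (1 - rho_eff + rho_eff * S))
  as.numeric(out)
}

# leading eigenpair with Perron sign fixing; flags non-positive eigenvectors
leading_eigen <- function(C) {
  e <- eigen(C)
  i <- which.max(Re(e$values))
  complex_pair <- abs(Im(e$values[i])) > 1e-9 * max(1, abs(Re(e$values[i])))
  v <- Re(e$vectors[, i])
  v <- v / sqrt(sum(v^2))
  if (sum(v) < 0) v <- -v
  list(lambda1 = Re(e$values[i]), v1 = v,
       positive = all(v > 0), complex_pair = complex_pair)
}

#' Species vulnerabilities and the feasibility condition
#'
#' The vulnerability of species `i` under productivity vector `p` is the
#' normalized deficit relative to the optimal (Perron-aligned) productivity
#' profile,
#' \deqn{\eta_i = 1 - \frac{p_i}{p^1 v^1_i},}
#' where `v1` is the unit-norm leading eigenvector of the effective
#' competition matrix and `p1 = <p, v1>` the projection of `p` on it. The
#' `(v1_i)^2`-weighted average of the vulnerabilities is identically zero.
#' Sufficient condition for every equilibrium abundance to exceed `n_c` is
#' `max_i eta_i <= eta_crit * (1 - n_c / mean(n))` (exact in mean field),
#' with `eta_crit = S_eff/(S_eff + S)`; `n_c = 0` gives the plain feasibility
#' condition.
#'
#' @param C Diagonal-normalized effective competition matrix.
#' @param p Productivity vector.
#' @param n_c Viability threshold abundance (default 0).
#' @return List with `eta` (vector), `eta_max`, `eta_crit`, `feasible`
#'   (verdict of the sufficient condition), `lambda1`, `v1`, `rho_eff`,
#'   `S_eff`, and flags `perron_ok`, `complex_pair`.
#' @export
vulnerabilities <- function(C, p, n_c = 0) {
  le <- leading_eigen(C)
  if (!le$positive) {
    warning("leading eigenvector is not strictly positive (Perron failure); vulnerabilities are unreliable",
            call. = FALSE)
  }
  p1 <- sum(p * le$v1)
  if (p1 <= 0) {
    abort_domain("non-positive projection of the productivity on the leading eigenvector",
                 class = "mutualstab_degenerate_error")
  }
  eta <- 1 - p / (p1 * le$v1)
  r_eff <- rho_eff(C)
  ec <- eta_crit(r_eff, nrow(C))
  thr <- ec
  if (n_c > 0) {
    n_eq <- solve(C, p)
    thr <- ec * (1 - n_c / mean(n_eq))
  }
  list(eta = eta, eta_max = max(eta), eta_crit = ec, threshold = thr,
       feasible = max(eta) <= thr, lambda1 = le$lambda1, v1 = le$v1,
       rho_eff = r_eff, S_eff = (1 - r_eff) / r_eff,
       perron_ok = le$positive, complex_pair = le$complex_pair)
}

# reduce one guild: C = beta_f - gLV_f beta_o^{-1} gLV_o, p = aLV_f + gLV_f beta_o^{-1} aLV_o,
# then normalize to unit diagonal (similarity D^-1/2 C D^-1/2 with D = diag(C))
reduce_guild <- function(beta_f, gLV_f, gLV_o, aLV_f, aLV_o, beta_o_inv,
                         nstar_f) {
  G <- unname(gLV_f) %*% beta_o_inv
  C_raw <- unname(beta_f) - G %*% unname(gLV_o)
  p_raw <- as.vector(unname(aLV_f) + G %*% aLV_o)
  resid <- max(abs(C_raw %*% nstar_f - p_raw))
  d <- diag(C_raw)
  if (any(d <= 0)) {
    abort_domain("non-positive diagonal in the effective competition matrix",
                 class = "mutualstab_degenerate_error")
  }
  s <- sqrt(d)
  C <- C_raw / outer(s, s)            # D^{-1/2} C D^{-1/2}
  p <- p_raw / s
  n <- s * nstar_f                    # so that C n = p still holds
  vul <- vulnerabilities(C, p)
  c(list(C = C, p = p, nstar = n, G = G / s, residual = resid, scale = s), vul)
}

#' Effective single-guild competition systems
#'
#' Eliminates each guild in turn from the linearized two-guild system: the
#' surviving guild obeys `C n* = p` with effective competition
#' `C = beta - gammaLV (beta_other)^{-1} gammaLV_other` and productivity
#' `p = alphaLV + gammaLV (beta_other)^{-1} alphaLV_other`. Matrices are
#' reported in units of unit intraspecific effective competition
#' (`C_ii = 1`, the same similarity applied to `p` and `n*`), with spectral
#' summaries and vulnerabilities attached.
#'
#' @param lv An [equivalent_lv()] object (or a `mutual_community`).
#' @return An `effective_system` object with sub-lists `plants` and `animals`
#'   (`C`, `p`, `nstar`, `G`, `lambda1`, `v1`, `rho_eff`, `S_eff`, `eta`,
#'   `eta_crit`, `feasible`, residual and degeneracy flags) plus the `lv`
#'   system it came from.
#' @export
effective_system <- function(lv) {
  if (inherits(lv, "mutual_community")) lv <- equivalent_lv(lv)
  comm <- lv$comm
  inv_A <- tryCatch(solve(comm$beta_A), error = function(e)
    abort_domain("animal competition matrix is singular"))
  inv_P <- tryCatch(solve(comm$beta_P), error = function(e)
    abort_domain("plant competition matrix is singular"))
  plants <- reduce_guild(comm$beta_P, lv$gammaLV_P, lv$gammaLV_A,
                         lv$alphaLV_P, lv$alphaLV_A, inv_A, comm$n_P)
  animals <- reduce_guild(comm$beta_A, lv$gammaLV_A, lv$gammaLV_P,
                          lv$alphaLV_A, lv$alphaLV_P, inv_P, comm$n_A)
  res <- max(plants$residual, animals$residual)
  if (res > 1e-8) {
    abort_domain(sprintf("effective equilibrium identity violated (residual %.2e)", res))
  }
  structure(list(plants = plants, animals = animals, lv = lv),
            class = "effective_system")
}

#' @export
print.effective_system <- function(x, ...) {
  cat(sprintf(
    "<effective_system> rho_eff: plants %.4f, animals %.4f | eta_crit: %.4f, %.4f | eta_max: %.4f, %.4f\n",
    x$plants$rho_eff, x$animals$rho_eff,
    x$plants$eta_crit, x$animals$eta_crit,
    x$plants$eta_max, x$animals$eta_max))
  invisible(x)
}

#' @rdname effective_system
#' @param x An `effective_system`.
#' @param ... Ignored.
#' @export
tidy.effective_system <- function(x, ...) {
  comm <- x$lv$comm
  dplyr::bind_rows(
    tibble::tibble(guild = "plants", species = comm$net$plants,
                   degree = degrees(comm$net, "plants"),
                   alpha = comm$alpha_P, z = comm$z_P,
                   regime = comm$regime_P, nstar = comm$n_P,
                   eta = x$plants$eta, v1 = x$plants$v1),
    tibble::tibble(guild = "animals", species = comm$net$animals,
                   degree = degrees(comm$net, "animals"),
                   alpha = comm$alpha_A, z = comm$z_A,
                   regime = comm$regime_A, nstar = comm$n_A,
                   eta = x$animals$eta, v1 = x$animals$v1)
  )
}

#' @rdname effective_system
#' @export
glance.effective_system <- function(x, ...) {
  tibble::tibble(
    rho_eff_P = x$plants$rho_eff, rho_eff_A = x$animals$rho_eff,
    S_eff_P = x$plants$S_eff, S_eff_A = x$animals$S_eff,
    eta_crit_P = x$plants$eta_crit, eta_crit_A = x$animals$eta_crit,
    eta_max_P = x$plants$eta_max, eta_max_A = x$animals$eta_max,
    feasible_P = x$plants$feasible, feasible_A = x$animals$feasible,
    perron_ok = x$plants$perron_ok && x$animals$perron_ok
  )
}
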