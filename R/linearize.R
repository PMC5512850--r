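#' Equivalent Lotka-Volterra system at the equilibrium
#'
#' Linearizes the saturating mutualistic term around the fixed point: the
#' effective mutualistic strengths are the derivatives of the functional
#' response at equilibrium, `gammaLV_ik = gamma_ik / (1 + z_i)^2`, and the
#' saturation offsets `m_i = (1/h_i) (z_i/(1+z_i))^2` shift the growth rates,
#' `alphaLV_i = alpha_i + m_i`. The resulting Lotka-Volterra system has the
#' same fixed point and the same Jacobian at the fixed point as the full model.
#'
#' @param comm A `mutual_community` from [build_community()].
#' @return An `equivalent_lv` object with `z`, `gammaLV_P`, `gammaLV_A`, `m_P`,
#'   `m_A`, `alphaLV_P`, `alphaLV_A`, the full interaction matrix `A`
#'   (plants first; competitive blocks negative, mutualistic blocks positive)
#'   and the community matrix `J = diag(N*) A`.
#' @export
equivalent_lv <- function(comm) {
  sat_P <- (1 + comm$z_P)^2
  sat_A <- (1 + comm$z_A)^2
  gammaLV_P <- comm$gamma_P / sat_P   # row-wise division
  gammaLV_A <- comm$gamma_A / sat_A
  m_P <- if (comm$h_P[1] > 0) (1 / comm$h_P[1]) * (comm$z_P / (1 + comm$z_P))^2 else comm$z_P * 0
  m_A <- if (comm$h_A[1] > 0) (1 / comm$h_A[1]) * (comm$z_A / (1 + comm$z_A))^2 else comm$z_A * 0
  A <- rbind(cbind(-comm$beta_P, gammaLV_P),
             cbind(gammaLV_A, -comm$beta_A))
  nstar <- c(comm$n_P, comm$n_A)
  structure(list(
    comm = comm,
    z_P = comm$z_P, z_A = comm$z_A,
    gammaLV_P = gammaLV_P, gammaLV_A = gammaLV_A,
    m_P = m_P, m_A = m_A,
    alphaLV_P = comm$alpha_P + m_P,
    alphaLV_A = comm$alpha_A + m_A,
    A = A, J = nstar * A, nstar = nstar
  ), class = "equivalent_lv")
}

#' Local (dynamical) stability of the equilibrium
#'
#' The equilibrium is locally stable when all eigenvalues of the community
#' matrix `J = diag(N*) A` have negative real parts.
#'
#' @param lv An [equivalent_lv()] object (or a `mutual_community`, linearized
#'   on the fly).
#' @return List with `stable` (logical) and `lambda_max` (largest real part).
#' @export
local_stability <- function(lv) {
  if (inherits(lv, "mutual_community")) lv <- equivalent_lv(lv)
  if (any(!is.finite(lv$J))) abort_domain("non-finite entries in the community matrix")
  lambda <- eigen(lv$J, only.values = TRUE)$values
  lmax <- max(Re(lambda))
  list(stable = lmax < 0, lambda_max = lmax)
}

#' Diagonal-stability certificate (sufficient global-stability test)
#'
#' Diagonal stability of the LV interaction matrix (a positive diagonal `D`
#' with `DA + t(A)D` negative definite) guarantees global stability of the
#' feasible equilibrium. Deciding it exactly is a linear matrix inequality;
#' this function returns a tri-state verdict from cheap tests:
#' `certified_stable` when the symmetric part of `DA` is negative definite for
#' `D = I` or for a per-guild diagonal rescaling found by a line search;
#' `certified_not` when a necessary condition fails (a non-negative diagonal
#' entry, or a 2x2 principal submatrix with non-positive "determinant" —
#' principal submatrices of diagonally stable matrices are diagonally stable);
#' `inconclusive` otherwise. The certificate never claims completeness.
#'
#' @param A Square interaction matrix (as in [equivalent_lv()]`$A`).
#' @param S_P Size of the leading (plant) block used by the per-guild scaling
#'   search; `NULL` skips that search.
#' @return List with `verdict` and, when certified stable, the scaling `d`.
#' @export
diagonal_stability_certificate <- function(A, S_P = NULL) {
  S <- nrow(A)
  if (any(diag(A) >= 0)) return(list(verdict = "certified_not", d = NULL))
  # 2x2 principal minors of -A must be positive (P-matrix necessary condition)
  m2 <- outer(diag(A), diag(A)) - A * t(A)
  if (any(m2[upper.tri(m2)] <= 0)) return(list(verdict = "certified_not", d = NULL))

  negdef <- function(d) {
    Sym <- d * A; Sym <- (Sym + t(Sym)) / 2
    max(eigen(Sym, symmetric = TRUE, only.values = TRUE)$values) < 0
  }
  if (negdef(rep(1, S))) return(list(verdict = "certified_stable", d = rep(1, S)))
  if (!is.null(S_P) && S_P < S) {
    for (r in 10^seq(-3, 3, length.out = 25)) {
      d <- c(rep(1, S_P), rep(r, S - S_P))
      if (negdef(d)) return(list(verdict = "certified_stable", d = d))
    }
  }
  list(verdict = "inconclusive", d = NULL)
}

#' Bracket the critical mutualistic strengths
#'
#' Scans the mutualism scale `gamma0` over a logarithmic grid for a fixed,
#' typical realization of the random coefficient draws, locating the stability
#' boundaries of the equilibrium: the equilibrium is stable below a lower
#' critical strength and again above an upper one (the effective mutualistic
#' interactions peak at intermediate saturation). Each boundary found on the
#' grid is refined by bisection on the sign of the leading eigenvalue.
#'
#' @param net A [bipartite_network()].
#' @param meta A [meta_parameters()] object (its `gamma0` is ignored).
#' @param seed Integer seed fixing the coefficient realization across the scan.
#' @param grid Increasing positive `gamma0` values to scan.
#' @param tol Bisection tolerance on `gamma0`.
#' @return List with `gamma_minus`, `gamma_plus` (NA when not found),
#'   `all_stable` flag, and the scan as a tibble
#'   (`gamma0`, `lambda_max`, `stable`).
#' @export
critical_gamma_bracket <- function(net, meta, seed = 1L,
                                   grid = 10^seq(-3, 2, length.out = 50),
                                   tol = 1e-4) {
  net <- as_network(net)
  probe <- function(g0) {
    m <- meta; m$gamma0 <- g0
    comm <- build_community(net, m, seed = seed, enforce_regime = FALSE)
    local_stability(comm)$lambda_max
  }
  lam <- vapply(grid, probe, numeric(1))
  scan <- tibble::tibble(gamma0 = grid, lambda_max = lam, stable = lam < 0)
  if (all(scan$stable)) {
    return(list(gamma_minus = NA_real_, gamma_plus = NA_real_,
                all_stable = TRUE, scan = scan))
  }
  bisect <- function(lo, hi, stable_lo) {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if ((probe(mid) < 0) == stable_lo) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  unstable <- which(!scan$stable)
  g_minus <- NA_real_; g_plus <- NA_real_
  first_u <- unstable[1]
  if (first_u > 1) {
    g_minus <- bisect(grid[first_u - 1], grid[first_u], stable_lo = TRUE)
  }
  last_u <- unstable[length(unstable)]
  if (last_u < length(grid)) {
    g_plus <- bisect(grid[last_u], grid[last_u + 1], stable_lo = FALSE)
  }
  list(gamma_minus = g_minus, gamma_plus = g_plus, all_stable = FALSE,
       scan = scan)
}
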