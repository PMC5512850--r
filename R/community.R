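#' Meta-parameters of the mutualistic community model
#'
#' Collects the meta-parameters that define the dynamical system in rescaled
#' units (intraspecific competition 1, guild-mean abundances 1):
#' direct interspecific competition `rho_P`, `rho_A` (relative to
#' intraspecific), mutualism scale `gamma0`, dimensionless saturation
#' meta-parameters `sat_P`, `sat_A` (the handling scale; `1/h` is the maximum
#' mutualistic growth rate), the half-widths `delta_b`, `delta_c`, `delta_N` of
#' the uniform distributions of the interaction coefficients and of the
#' equilibrium abundances, and the plant/animal abundance-scale ratio
#' `ratio_PA` used by obligatory mutualism.
#'
#' For `mutualism = "obligatory_animals"` the saturation scales are overridden
#' at assembly time by [choose_saturation()]: `h_A = 0.75 / (S_A rho_A + 1 -
#' rho_A)` (slightly below the feasibility ceiling on the handling time) and
#' `h_P = 0.25`; `ratio_PA` must exceed the bound of
#' [obligatory_abundance_bound()] so that solved animal growth rates come out
#' negative.
#'
#' @param rho_P,rho_A Interspecific/intraspecific competition ratios in `[0,1)`.
#' @param gamma0 Mutualism strength scale (>= 0).
#' @param sat_P,sat_A Dimensionless saturation meta-parameters (facultative
#'   regimes; 1 = default, 100 = strong-mutualism setting).
#' @param delta_b,delta_c,delta_N Uniform half-widths in `[0, 1)`.
#' @param ratio_PA Plant-to-animal abundance-scale ratio (used when
#'   `mutualism = "obligatory_animals"`; ignored otherwise, where it is 1).
#' @param mutualism `"facultative"` or `"obligatory_animals"`.
#' @return A `meta_parameters` list.
#' @export
meta_parameters <- function(rho_P = 0.05, rho_A = rho_P, gamma0 = 0.1,
                            sat_P = 1, sat_A = sat_P,
                            delta_b = 0.1, delta_c = 0.1, delta_N = 0.15,
                            ratio_PA = 1e6,
                            mutualism = c("facultative", "obligatory_animals")) {
  mutualism <- match.arg(mutualism)
  assert_fraction(rho_P, "rho_P", open_upper = TRUE)
  assert_fraction(rho_A, "rho_A", open_upper = TRUE)
  if (gamma0 < 0) abort_domain("`gamma0` must be non-negative")
  assert_fraction(delta_b, "delta_b", open_upper = TRUE)
  assert_fraction(delta_c, "delta_c", open_upper = TRUE)
  assert_fraction(delta_N, "delta_N", open_upper = TRUE)
  assert_positive(sat_P, "sat_P"); assert_positive(sat_A, "sat_A")
  assert_positive(ratio_PA, "ratio_PA")
  structure(list(rho_P = rho_P, rho_A = rho_A, gamma0 = gamma0,
                 sat_P = sat_P, sat_A = sat_A,
                 delta_b = delta_b, delta_c = delta_c, delta_N = delta_N,
                 ratio_PA = if (mutualism == "facultative") 1 else ratio_PA,
                 mutualism = mutualism),
            class = "meta_parameters")
}

#' Direct competition matrix
#'
#' Fully connected competition matrix in rescaled units: diagonal exactly 1,
#' off-diagonal `rho * b_ij` with `b_ij ~ Uniform[1 - delta_b, 1 + delta_b]`.
#'
#' @param S Number of species.
#' @param rho Interspecific/intraspecific ratio in `[0, 1)`.
#' @param delta_b Uniform half-width.
#' @param seed Optional integer seed.
#' @export
build_competition <- function(S, rho, delta_b = 0, seed = NULL) {
  assert_fraction(rho, "rho", open_upper = TRUE)
  local_seed(seed, {
    b <- matrix(stats::runif(S * S, 1 - delta_b, 1 + delta_b), S, S)
    beta <- rho * b
    diag(beta) <- 1
    beta
  })
}

#' Mutualistic interaction matrices
#'
#' Non-zero exactly on the links of the network: `gamma_ik = gamma0 * scale *
#' c_ik` with independent `c ~ Uniform[1 - delta_c, 1 + delta_c]` draws on each
#' side. In rescaled units the plant-side matrix carries the factor
#' `sqrt(1/ratio_PA)` and the animal-side matrix `sqrt(ratio_PA)`, so that for
#' facultative mutualism (`ratio_PA = 1`) both sides have scale `gamma0`, while
#' a large plant-to-animal abundance ratio pushes animals towards saturation
#' (the obligatory weak-strong setting).
#'
#' @param net A [bipartite_network()].
#' @param gamma0 Mutualism scale.
#' @param delta_c Uniform half-width.
#' @param ratio_PA Plant/animal abundance-scale ratio.
#' @param seed Optional integer seed.
#' @return List with `gamma_P` (plants x animals) and `gamma_A`
#'   (animals x plants).
#' @export
build_mutualism <- function(net, gamma0, delta_c = 0, ratio_PA = 1,
                            seed = NULL) {
  net <- as_network(net)
  if (gamma0 < 0) abort_domain("`gamma0` must be non-negative")
  a <- net$incidence
  local_seed(seed, {
    cP <- matrix(stats::runif(length(a), 1 - delta_c, 1 + delta_c), nrow(a))
    cA <- matrix(stats::runif(length(a), 1 - delta_c, 1 + delta_c), ncol(a))
    list(gamma_P = gamma0 / sqrt(ratio_PA) * cP * a,
         gamma_A = gamma0 * sqrt(ratio_PA) * cA * t(a))
  })
}

#' Saturation (handling) scales per regime
#'
#' Facultative regimes use the dimensionless saturation meta-parameter as the
#' handling scale for both guilds. For mutualism obligatory for animals the
#' animal handling scale is set slightly below its feasibility ceiling,
#' `h_A = 0.75 / (S_A rho_A + 1 - rho_A)` (so the maximum mutualistic growth
#' rate `1/h_A` exceeds the equilibrium competition load by a 4/3 margin), and
#' the plant scale is `h_P = 0.25`, all in rescaled abundance units.
#'
#' @param meta A [meta_parameters()] object.
#' @param S_A Number of animal species.
#' @return List with scalars `h_P`, `h_A`.
#' @export
choose_saturation <- function(meta, S_A) {
  if (meta$mutualism == "obligatory_animals") {
    h_A <- 0.75 / (S_A * meta$rho_A + 1 - meta$rho_A)
    if (h_A <= 0) abort_domain("non-positive animal handling scale")
    list(h_P = 0.25, h_A = h_A)
  } else {
    list(h_P = meta$sat_P, h_A = meta$sat_A)
  }
}

#' Draw equilibrium abundances
#'
#' `N*_i = e_i` in rescaled units (guild mean 1), with `e_i` uniform on
#' `[1 - delta_N, 1 + delta_N]` by default, or log-normal with matching mean
#' and coefficient of variation.
#'
#' @param S Number of species.
#' @param delta_N Half-width (uniform) or the matched relative spread
#'   (lognormal).
#' @param distribution `"uniform"` or `"lognormal"`.
#' @param seed Optional integer seed.
#' @export
draw_abundances <- function(S, delta_N = 0.15,
                            distribution = c("uniform", "lognormal"),
                            seed = NULL) {
  distribution <- match.arg(distribution)
  if (distribution == "uniform") assert_fraction(delta_N, "delta_N", open_upper = TRUE)
  local_seed(seed, {
    switch(distribution,
           uniform = stats::runif(S, 1 - delta_N, 1 + delta_N),
           lognormal = {
             sdlog <- sqrt(log(1 + delta_N^2 / 3))  # match uniform variance
             stats::rlnorm(S, meanlog = -sdlog^2 / 2, sdlog = sdlog)
           })
  })
}

# saturating mutualistic growth term and its saturation factor z;
# h = 0 is the linear (no saturation) limit
mutualistic_term <- function(gamma, n_other, h) {
  inflow <- as.vector(gamma %*% n_other)
  z <- h * inflow
  M <- if (h > 0) (1 / h) * z / (1 + z) else inflow
  list(z = z, M = M)
}

#' Assemble a model community on a network
#'
#' Draws interaction coefficients and equilibrium abundances, then solves for
#' the intrinsic growth rates that make the drawn abundances an exact fixed
#' point of the dynamics (feasibility by construction). Species are classified
#' weak (`z <= z_strong`) or strong mutualists from their equilibrium
#' saturation factor `z_i = h_i * sum_k gamma_ik N*_k`.
#'
#' @param net A [bipartite_network()].
#' @param meta A [meta_parameters()] object.
#' @param seed Optional integer seed.
#' @param distribution Abundance distribution, see [draw_abundances()].
#' @param z_strong Threshold on `z` separating the weak and strong labels
#'   (reported, never silently used).
#' @param enforce_regime Check the obligatory-mutualism sign contract
#'   (`alpha_A < 0`, `alpha_P > 0`)? Disabled by stability scans that sweep
#'   `gamma0` through values where the contract cannot hold.
#' @return A `mutual_community` object: network, meta, matrices `beta_P`,
#'   `beta_A`, `gamma_P`, `gamma_A`, handling vectors `h_P`, `h_A`, equilibrium
#'   abundances `n_P`, `n_A`, growth rates `alpha_P`, `alpha_A`, saturation
#'   factors `z_P`, `z_A` and regime labels.
#' @export
build_community <- function(net, meta = meta_parameters(), seed = NULL,
                            distribution = "uniform", z_strong = 1,
                            enforce_regime = TRUE) {
  net <- as_network(net)
  S_P <- n_plants(net); S_A <- n_animals(net)
  sat <- choose_saturation(meta, S_A)
  local_seed(seed, {
    beta_P <- build_competition(S_P, meta$rho_P, meta$delta_b)
    beta_A <- build_competition(S_A, meta$rho_A, meta$delta_b)
    gm <- build_mutualism(net, meta$gamma0, meta$delta_c, meta$ratio_PA)
    n_P <- draw_abundances(S_P, meta$delta_N, distribution)
    n_A <- draw_abundances(S_A, meta$delta_N, distribution)
    comm <- structure(list(
      net = net, meta = meta,
      beta_P = beta_P, beta_A = beta_A,
      gamma_P = gm$gamma_P, gamma_A = gm$gamma_A,
      h_P = rep(sat$h_P, S_P), h_A = rep(sat$h_A, S_A),
      n_P = n_P, n_A = n_A), class = "mutual_community")
    solve_growth_rates(comm, z_strong = z_strong,
                       enforce_regime = enforce_regime)
  })
}

#' Solve intrinsic growth rates for a feasible fixed point
#'
#' Sets `alpha_i = sum_j beta_ij N*_j - M_i(N*)` so that the drawn abundances
#' are an exact equilibrium of the dynamics, where `M_i` is the saturating
#' mutualistic growth term. For obligatory (animal) mutualism the sign contract
#' `alpha_A < 0`, `alpha_P > 0` is verified and violations raise an error that
#' names the offending species.
#'
#' @param comm A partially assembled `mutual_community` (without `alpha`).
#' @param z_strong Weak/strong classification threshold on `z`.
#' @param enforce_regime Check the obligatory sign contract?
#' @return The community, completed with `alpha_P`, `alpha_A`, `z_P`, `z_A`,
#'   `regime_P`, `regime_A` and a checked `residual`.
#' @export
solve_growth_rates <- function(comm, z_strong = 1, enforce_regime = TRUE) {
  mt_P <- mutualistic_term(comm$gamma_P, comm$n_A, comm$h_P[1])
  mt_A <- mutualistic_term(comm$gamma_A, comm$n_P, comm$h_A[1])
  comm$alpha_P <- as.vector(comm$beta_P %*% comm$n_P) - mt_P$M
  comm$alpha_A <- as.vector(comm$beta_A %*% comm$n_A) - mt_A$M
  comm$z_P <- mt_P$z
  comm$z_A <- mt_A$z
  comm$regime_P <- ifelse(comm$z_P > z_strong, "strong", "weak")
  comm$regime_A <- ifelse(comm$z_A > z_strong, "strong", "weak")
  res <- max(abs(community_rhs(comm, c(comm$n_P, comm$n_A), per_capita = TRUE)))
  if (!is.finite(res) || res > 1e-10) {
    abort_domain(sprintf("fixed-point residual %.3e exceeds 1e-10", res))
  }
  comm$residual <- res
  if (enforce_regime && comm$meta$mutualism == "obligatory_animals") {
    bad_A <- which(comm$alpha_A >= 0)
    bad_P <- which(comm$alpha_P <= 0)
    if (length(bad_A) || length(bad_P)) {
      abort_domain(sprintf(
        "obligatory-mutualism regime violated (animals with alpha >= 0: %s; plants with alpha <= 0: %s); increase ratio_PA above obligatory_abundance_bound()",
        paste(comm$net$animals[bad_A], collapse = ",") %||% "",
        paste(comm$net$plants[bad_P], collapse = ",") %||% ""),
        class = "mutualstab_regime_error")
    }
  }
  comm
}

#' @export
print.mutual_community <- function(x, ...) {
  cat(sprintf(
    "<mutual_community> %d plants + %d animals | rho = (%.3g, %.3g), gamma0 = %.3g, %s\n",
    length(x$n_P), length(x$n_A), x$meta$rho_P, x$meta$rho_A, x$meta$gamma0,
    x$meta$mutualism))
  cat(sprintf("  saturation z: plants [%.3g, %.3g], animals [%.3g, %.3g]\n",
              min(x$z_P), max(x$z_P), min(x$z_A), max(x$z_A)))
  invisible(x)
}

#' Right-hand side of the community dynamics
#'
#' Evaluates `dN/dt` (or the per-capita growth rate) of the saturating
#' mutualistic Lotka-Volterra model at a state vector `n` (plants first).
#'
#' @param comm A `mutual_community`.
#' @param n State vector of length `S_P + S_A`.
#' @param per_capita Return per-capita rates instead of `dN/dt`?
#' @export
community_rhs <- function(comm, n, per_capita = FALSE) {
  S_P <- length(comm$n_P)
  nP <- n[seq_len(S_P)]
  nA <- n[-seq_len(S_P)]
  gP <- mutualistic_term(comm$gamma_P, nA, comm$h_P[1])$M
  gA <- mutualistic_term(comm$gamma_A, nP, comm$h_A[1])$M
  per <- c(comm$alpha_P - as.vector(comm$beta_P %*% nP) + gP,
           comm$alpha_A - as.vector(comm$beta_A %*% nA) + gA)
  if (per_capita) per else n * per
}

#' Feasibility bound on the plant/animal abundance ratio
#'
#' Closed-form evaluation of the obligatory-mutualism feasibility requirement:
#' an obligate animal with mutualistic degree `d_min` keeps a negative intrinsic
#' growth rate only if its equilibrium saturation factor exceeds
#' `u/(1-u)` with `u = h_A (S_A rho_A + 1 - rho_A)`, which with
#' `h_A = 0.75/(S_A rho_A + 1 - rho_A)` translates into a lower bound on the
#' plant-to-animal abundance-scale ratio:
#' \deqn{N_P/N_A > \left(\frac{u/(1-u)}{h_A \gamma_0 d_{\min}}\right)^2 = \left(\frac{3}{h_A \gamma_0 d_{\min}}\right)^2.}
#' At `S_A = 50`, `rho_A = 0.25`, `gamma0 = 0.1`, `d_min = 1` this evaluates to
#' about `2.8e5`, of the order of the ratios observed between plant and
#' pollinator biomasses.
#'
#' @param S_A Number of animal species.
#' @param rho_A Animal direct competition.
#' @param gamma0 Mutualism scale.
#' @param d_min Smallest animal mutualistic degree.
#' @param margin Saturation margin `u` (default 0.75, matching the `h_A`
#'   choice).
#' @return The minimal admissible abundance ratio `N_P/N_A`.
#' @export
obligatory_abundance_bound <- function(S_A, rho_A, gamma0, d_min = 1,
                                       margin = 0.75) {
  h_A <- margin / (S_A * rho_A + 1 - rho_A)
  ((margin / (1 - margin)) / (h_A * gamma0 * d_min))^2
}

#' Rescale a system to unit intraspecific competition
#'
#' Transforms a system given in arbitrary units (positive intraspecific
#' competition coefficients `beta_ii`, arbitrary abundance units) into the
#' mathematically equivalent system with `beta_ii = 1` through the per-species
#' change of units `n_i = beta_ii N_i`. Trajectories of the two systems
#' correspond exactly under this map; applying the transformation twice is the
#' identity.
#'
#' @param sys List with `beta_P`, `beta_A` (positive diagonals), `gamma_P`,
#'   `gamma_A`, `h_P`, `h_A`, `alpha_P`, `alpha_A`, `N_P`, `N_A`.
#' @return The same structure in rescaled units, plus `scale_P`, `scale_A` (the
#'   per-species multipliers `beta_ii`).
#' @export
rescale_units <- function(sys) {
  dP <- diag(sys$beta_P); dA <- diag(sys$beta_A)
  if (any(dP <= 0) || any(dA <= 0)) {
    abort_domain("intraspecific competition coefficients must be positive")
  }
  list(
    beta_P = sweep(sys$beta_P, 2, dP, "/"),
    beta_A = sweep(sys$beta_A, 2, dA, "/"),
    gamma_P = sweep(sys$gamma_P, 2, dA, "/"),
    gamma_A = sweep(sys$gamma_A, 2, dP, "/"),
    h_P = sys$h_P, h_A = sys$h_A,
    alpha_P = sys$alpha_P, alpha_A = sys$alpha_A,
    N_P = dP * sys$N_P, N_A = dA * sys$N_A,
    scale_P = dP, scale_A = dA
  )
}
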