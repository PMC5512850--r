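#' Perturb intrinsic growth rates
#'
#' Environmental perturbations of relative amplitude `Delta`:
#' `alpha_i' = alpha_i (1 + Delta r_i)` with `r_i` uniform on `[-1, 1]`
#' (the simulation protocol) or normal with matching variance 1/3 (the
#' distribution used by the analytic propagation estimate).
#'
#' @param alpha Growth-rate vector.
#' @param Delta Relative perturbation amplitude (>= 0).
#' @param seed Optional integer seed.
#' @param dist `"uniform"` or `"normal"`.
#' @export
perturb_rates <- function(alpha, Delta, seed = NULL,
                          dist = c("uniform", "normal")) {
  dist <- match.arg(dist)
  if (Delta < 0) abort_domain("`Delta` must be non-negative")
  local_seed(seed, {
    r <- switch(dist,
                uniform = stats::runif(length(alpha), -1, 1),
                normal = stats::rnorm(length(alpha), 0, sqrt(1 / 3)))
    alpha * (1 + Delta * r)
  })
}

# productivities and per-guild max-vulnerability for perturbed growth rates,
# under the fixed-linearization approximation (gammaLV, C, eigensystem frozen)
eta_of_perturbation <- function(sys, alpha_P, alpha_A) {
  lv <- sys$lv
  pl <- sys$plants; an <- sys$animals
  aLV_P <- alpha_P + lv$m_P
  aLV_A <- alpha_A + lv$m_A
  p_P <- as.vector(aLV_P / pl$scale + pl$G %*% aLV_A)
  p_A <- as.vector(aLV_A / an$scale + an$G %*% aLV_P)
  eta_max <- function(p, v1) {
    p1 <- sum(p * v1)
    if (p1 <= 0) return(Inf)          # productivity profile degenerate
    max(1 - p / (p1 * v1))
  }
  c(plants = eta_max(p_P, pl$v1), animals = eta_max(p_A, an$v1))
}

#' Vulnerability response to growth-rate perturbations
#'
#' Perturbs all intrinsic growth rates by relative amplitude `Delta` and
#' returns, per guild, the mean over `n_reps` realizations of the maximal
#' vulnerability `eta(Delta) = max_i eta_i(p(Delta))`, keeping the effective
#' competition matrices and their eigensystems fixed at the unperturbed ones.
#' Replicate draws are indexed by replicate number, so calls at different
#' `Delta` under the same seed share perturbation directions (common random
#' numbers; this makes finite-difference slopes across `Delta` nearly
#' noise-free).
#'
#' @param sys An [effective_system()].
#' @param Delta Perturbation amplitude; `Delta = 0` returns the unperturbed
#'   vulnerability with no randomness.
#' @param n_reps Number of perturbation realizations.
#' @param seed Optional integer seed.
#' @param dist Perturbation distribution, see [perturb_rates()].
#' @return Tibble with one row per guild: `guild`, `Delta`, `eta_mean`,
#'   `eta_sd`, `n_reps`; attribute `"realizations"` holds the per-realization
#'   matrix.
#' @export
eta_response <- function(sys, Delta, n_reps = 100, seed = NULL,
                         dist = "uniform") {
  comm <- sys$lv$comm
  if (Delta == 0) {
    vals <- matrix(c(sys$plants$eta_max, sys$animals$eta_max), nrow = 1,
                   dimnames = list(NULL, c("plants", "animals")))
  } else {
    vals <- t(vapply(seq_len(n_reps), function(rep) {
      rep_seed <- child_seed(seed, rep)
      local_seed(rep_seed, {
        aP <- perturb_rates(comm$alpha_P, Delta, dist = dist)
        aA <- perturb_rates(comm$alpha_A, Delta, dist = dist)
        eta_of_perturbation(sys, aP, aA)
      })
    }, c(plants = 0, animals = 0)))
  }
  out <- tibble::tibble(
    guild = c("plants", "animals"),
    Delta = Delta,
    eta_mean = unname(colMeans(vals)),
    eta_sd = if (nrow(vals) > 1) unname(apply(vals, 2, stats::sd)) else c(0, 0),
    n_reps = nrow(vals)
  )
  attr(out, "realizations") <- vals
  out
}

#' Propagation of perturbations and unperturbed vulnerability
#'
#' Fits the linear response `eta(Delta) ~ eta_v + Delta * eta_prime` per guild
#' from two probe amplitudes placed around the feasibility threshold,
#' `Delta_0 = eta_crit - 0.05` and `Delta_1 = eta_crit + 0.05` (shifted, with
#' a warning, when `eta_crit <= 0.05`):
#' `eta_prime = (eta(Delta_1) - eta(Delta_0)) / (Delta_1 - Delta_0)` and
#' `eta_v = eta(Delta_0) - Delta_0 * eta_prime`.
#'
#' @inheritParams eta_response
#' @return Tibble with one row per guild: `eta_prime`, `eta_v`, the probe
#'   points and the probed means.
#' @export
eta_line <- function(sys, n_reps = 100, seed = NULL, dist = "uniform") {
  probes <- function(ec) {
    d0 <- ec - 0.05; d1 <- ec + 0.05
    if (d0 <= 0) {
      warning("eta_crit <= 0.05: probe points shifted to stay positive",
              call. = FALSE)
      d0 <- ec / 2; d1 <- ec
      if (d1 <= 0) { d0 <- 0.025; d1 <- 0.075 }
    }
    c(d0, d1)
  }
  pr_P <- probes(sys$plants$eta_crit)
  pr_A <- probes(sys$animals$eta_crit)
  deltas <- sort(unique(c(pr_P, pr_A)))
  resp <- lapply(deltas, function(d) eta_response(sys, d, n_reps, seed, dist))
  look <- function(guild, d) {
    for (r in seq_along(deltas)) {
      if (deltas[r] == d) return(resp[[r]]$eta_mean[resp[[r]]$guild == guild])
    }
  }
  line_for <- function(guild, pr) {
    e0 <- look(guild, pr[1]); e1 <- look(guild, pr[2])
    slope <- (e1 - e0) / (pr[2] - pr[1])
    tibble::tibble(guild = guild, eta_prime = slope,
                   eta_v = e0 - pr[1] * slope,
                   Delta0 = pr[1], Delta1 = pr[2], eta0 = e0, eta1 = e1)
  }
  dplyr::bind_rows(line_for("plants", pr_P), line_for("animals", pr_A))
}

#' Analytic estimate of the propagation of perturbations
#'
#' Variance-propagation estimate of `eta_prime`: a perturbation of amplitude
#' `Delta` shifts the productivity of plant `i` by `Delta q_i` with
#' `Var(q_i) = (alphaLV_i)^2/3 + sum_k G_ik^2 (alphaLV_k^{other})^2 / 3`
#' (`G = gammaLV beta_other^{-1}`, uniform `r`), and the most vulnerable
#' species sets the slope, estimated as
#' `eta_prime ~ constant * max_i sqrt(Var(q_i)) / p_i^0` using the
#' flat-eigenvector approximation `v1_i ~ 1/sqrt(S)`. The estimate is
#' advisory: the undetermined constant is calibrated once against the numeric
#' [eta_line()] on a reference ensemble and the numeric slope remains
#' authoritative. Because `p_i^0` is a sum of `d_i + 1` positive terms while
#' `sqrt(Var(q_i))` is their root-sum-square, the estimate falls roughly like
#' `1/sqrt(d_i + 1)`: more mutualistic links damp the propagation, and
#' obligatory mutualism (where `alpha` and `m` have opposite signs, shrinking
#' `p^0`) amplifies it.
#'
#' @param sys An [effective_system()].
#' @param guild `"plants"` or `"animals"`.
#' @param constant Calibration constant; the default was fixed once against
#'   [eta_line()] on a facultative weak-mutualism reference ensemble.
#' @return The scalar estimate.
#' @export
analytic_eta_prime <- function(sys, guild = c("plants", "animals"),
                               constant = eta_prime_constant()) {
  guild <- match.arg(guild)
  lv <- sys$lv
  g <- sys[[guild]]
  aLV_f <- if (guild == "plants") lv$alphaLV_P else lv$alphaLV_A
  aLV_o <- if (guild == "plants") lv$alphaLV_A else lv$alphaLV_P
  var_q <- (aLV_f / g$scale)^2 / 3 +
    as.vector((g$G^2) %*% (aLV_o^2)) / 3
  p0 <- as.vector(aLV_f / g$scale + g$G %*% aLV_o)
  if (any(p0 <= 0)) {
    abort_domain("non-positive unperturbed productivity",
                 class = "mutualstab_degenerate_error")
  }
  constant * max(sqrt(var_q) / p0)
}

# calibration constant for analytic_eta_prime (see the methods vignette);
# median ratio eta_prime_numeric / raw estimate over a 20-network facultative
# weak-mutualism reference ensemble at study scale (spread 1.47-1.58)
eta_prime_constant <- function() 1.56

#' Calibrate the analytic propagation constant
#'
#' Ratio of the numeric slope [eta_line()] to the raw (constant = 1) analytic
#' estimate, summarized over a list of effective systems by the median.
#'
#' @param sys_list List of [effective_system()] objects.
#' @param guild Guild to calibrate on.
#' @param n_reps,seed Passed to [eta_line()].
#' @return Median ratio (the constant to use).
#' @export
calibrate_eta_prime <- function(sys_list, guild = "plants", n_reps = 100,
                                seed = 1L) {
  ratios <- vapply(seq_along(sys_list), function(i) {
    sys <- sys_list[[i]]
    num <- eta_line(sys, n_reps = n_reps, seed = child_seed(seed, i))
    num <- num$eta_prime[num$guild == guild]
    num / analytic_eta_prime(sys, guild, constant = 1)
  }, numeric(1))
  stats::median(ratios)
}

#' Obligatory-mutualism minimum plant abundance and sole-partner fraction
#'
#' For mutualism obligatory for animals, an animal whose diet is a single
#' plant dies unless that plant stays abundant enough to keep the animal's
#' perturbed growth rate non-negative. Near saturation the required plant
#' abundance grows with the perturbation amplitude as
#' `N_min(Delta)/<N_P> ~ 1 + zbar * h_A * |alpha_A| * Delta`, where `zbar` is
#' the saturation factor of a degree-1 animal at average plant abundance; the
#' returned `slope` is that linear coefficient. `phi` is the fraction of plant
#' species that are the sole partner of at least one animal. Facultative
#' systems return zeros.
#'
#' @param sys An [effective_system()] (or `mutual_community`).
#' @param Delta Amplitude at which to evaluate the ratio (default 0).
#' @return List with `ratio` (`N_min(Delta)/<N_P>`; 0 for facultative), `phi`,
#'   and `slope` (d ratio / d Delta).
#' @export
obligatory_min_abundance <- function(sys, Delta = 0) {
  comm <- if (inherits(sys, "effective_system")) sys$lv$comm else sys
  if (comm$meta$mutualism != "obligatory_animals") {
    return(list(ratio = 0, phi = 0, slope = 0))
  }
  a <- comm$net$incidence
  d_A <- colSums(a)
  sole <- unique(which(a[, d_A == 1, drop = FALSE] == 1L, arr.ind = TRUE)[, 1])
  phi <- length(sole) / nrow(a)
  h_A <- comm$h_A[1]
  gamma_scale <- comm$meta$gamma0 * sqrt(comm$meta$ratio_PA)
  zbar <- h_A * gamma_scale * mean(comm$n_P)
  slope <- zbar * h_A * mean(abs(comm$alpha_A))
  list(ratio = 1 + slope * Delta, phi = phi, slope = slope)
}
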