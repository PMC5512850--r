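#' Integrate the community dynamics to equilibrium
#'
#' Adaptive embedded Runge-Kutta (Dormand-Prince 5(4)) integration of the
#' saturating mutualistic Lotka-Volterra dynamics from given initial
#' abundances. A species whose abundance falls below `ext_frac` times its
#' initial value is declared extinct and clamped to zero for the remainder of
#' the run; integration stops when the largest per-capita growth rate among
#' extant species falls below `conv_tol` (equilibrium) or at `t_max`.
#'
#' @param comm A `mutual_community` (its `alpha` may have been perturbed).
#' @param n0 Initial abundances (plants first); defaults to the community's
#'   equilibrium.
#' @param ext_frac Extinction threshold as a fraction of the initial abundance.
#' @param conv_tol Convergence tolerance on the per-capita growth rates. Must
#'   stay about two orders of magnitude above `rtol`: the numerical state
#'   hovers at distance `~rtol` from the true equilibrium, so measured rates
#'   floor there and a tighter criterion would never fire. The default pair
#'   (`1e-6`, `1e-8`) puts detection five orders below typical dynamical
#'   rates; extinction-bound species keep the run alive regardless, since
#'   their own per-capita rates stay of order `alpha` until they cross the
#'   extinction threshold.
#' @param t_max Time horizon (a non-converged run returns
#'   `converged = FALSE`).
#' @param rtol,atol Local error tolerances of the step controller. The
#'   absolute tolerance must stay well below `ext_frac` times a typical
#'   abundance (so extinction calls are accurate) but not drastically below
#'   it, or species decaying towards the threshold force vanishing steps.
#' @param stop_on_extinction Return as soon as any species crosses the
#'   extinction threshold (used by the Monte-Carlo measurement, which only
#'   asks whether at least one extinction occurs).
#' @return List with `n` (final abundances), `extinct` (logical),
#'   `n_extinct`, `t`, `converged`, `steps`, `clamped` (negative-overshoot
#'   clamp count).
#' @export
integrate_to_equilibrium <- function(comm, n0 = NULL, ext_frac = 1e-8,
                                     conv_tol = 1e-6, t_max = 1e4,
                                     rtol = 1e-8, atol = 1e-10,
                                     stop_on_extinction = FALSE) {
  n0 <- n0 %||% c(comm$n_P, comm$n_A)
  if (any(n0 < 0)) abort_domain("initial abundances must be non-negative")
  out <- .integrate_community_cpp(comm$beta_P, comm$beta_A,
                                  comm$gamma_P, comm$gamma_A,
                                  comm$alpha_P, comm$alpha_A,
                                  comm$h_P[1], comm$h_A[1], n0,
                                  ext_frac, conv_tol, t_max, rtol, atol,
                                  max_steps = 2000000L,
                                  stop_on_extinction = stop_on_extinction)
  out$n_extinct <- sum(out$extinct)
  if (out$clamped > 0) {
    warning(sprintf("%d negative abundance(s) clamped during integration",
                    out$clamped), call. = FALSE)
  }
  out
}

#' Measure structural stability by Monte-Carlo perturbation
#'
#' For each amplitude `Delta` on a grid, perturbs all intrinsic growth rates
#' (`alpha_i (1 + Delta r_i)`, `r` uniform on `[-1, 1]`), integrates the
#' dynamics from the unperturbed equilibrium, and records the fraction `e` of
#' replicates with at least one extinction. The critical perturbation
#' `Delta_c` is the linear interpolation of the `e = 0.5` crossing; the grid
#' is refined around the crossing for `refine` rounds. Replicate perturbation
#' directions are shared across amplitudes (common random numbers), so `e` is
#' non-decreasing in `Delta` up to integration effects.
#'
#' @param comm A `mutual_community` (dynamically stable at its `gamma0`).
#' @param delta_grid Increasing positive amplitudes to probe.
#' @param n_pert Perturbation replicates per amplitude.
#' @param seed Integer seed (fixed seed gives an identical report).
#' @param refine Rounds of grid refinement around the `e = 0.5` crossing.
#' @param ... Passed to [integrate_to_equilibrium()].
#' @return A `stability_report`: list with `curve` (tibble `Delta`, `e`,
#'   `n_reps`), `delta_c`, `censored` (`"none"`, `"above"`, or `"below"`),
#'   `n_pert`, `seed`, and `records` (per-replicate extinction counts).
#' @export
measure_delta_c <- function(comm, delta_grid = seq(0.05, 0.6, by = 0.05),
                            n_pert = 100, seed = NULL, refine = 2, ...) {
  stopifnot(all(diff(delta_grid) > 0), all(delta_grid > 0))
  records <- list()
  e_at <- function(Delta) {
    ext <- vapply(seq_len(n_pert), function(rep) {
      rep_seed <- child_seed(seed, rep)
      pc <- comm
      local_seed(rep_seed, {
        pc$alpha_P <- perturb_rates(comm$alpha_P, Delta)
        pc$alpha_A <- perturb_rates(comm$alpha_A, Delta)
      })
      integrate_to_equilibrium(pc, stop_on_extinction = TRUE, ...)$n_extinct
    }, integer(1))
    records[[sprintf("%.6f", Delta)]] <<- ext
    mean(ext > 0)
  }
  e <- vapply(delta_grid, e_at, numeric(1))
  curve <- tibble::tibble(Delta = delta_grid, e = e)

  cross <- function(curve) {
    lo <- which(curve$e < 0.5)
    hi <- which(curve$e >= 0.5)
    if (!length(hi)) return(NULL)
    if (!length(lo) || min(hi) == 1) return(0L)   # crossing below the grid
    i <- max(lo[lo < min(hi)])
    c(i, min(hi))
  }
  for (round in seq_len(refine)) {
    br <- cross(curve)
    if (is.null(br) || identical(br, 0L)) break
    mid <- mean(curve$Delta[br])
    if (min(abs(curve$Delta - mid)) < 1e-6) break
    curve <- dplyr::arrange(
      dplyr::bind_rows(curve, tibble::tibble(Delta = mid, e = e_at(mid))),
      .data$Delta)
  }
  br <- cross(curve)
  if (is.null(br)) {
    delta_c <- NA_real_; censored <- "above"    # e never reaches 0.5
  } else if (identical(br, 0L)) {
    delta_c <- NA_real_; censored <- "below"    # e >= 0.5 already at grid min
  } else {
    d0 <- curve$Delta[br[1]]; d1 <- curve$Delta[br[2]]
    e0 <- curve$e[br[1]]; e1 <- curve$e[br[2]]
    delta_c <- d0 + (0.5 - e0) / (e1 - e0) * (d1 - d0)
    censored <- "none"
  }
  structure(list(curve = dplyr::mutate(curve, n_reps = n_pert),
                 delta_c = delta_c, censored = censored,
                 n_pert = n_pert, seed = seed, records = records),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> Delta_c = %s (%s), %d perturbations x %d amplitudes\n",
              ifelse(is.na(x$delta_c), "censored", sprintf("%.4f", x$delta_c)),
              x$censored, x$n_pert, nrow(x$curve)))
  invisible(x)
}

#' @rdname measure_delta_c
#' @param x A `stability_report`.
#' @param ... Ignored.
#' @export
tidy.stability_report <- function(x, ...) x$curve

#' @rdname measure_delta_c
#' @export
glance.stability_report <- function(x, ...) {
  tibble::tibble(delta_c = x$delta_c, censored = x$censored,
                 n_pert = x$n_pert, n_amplitudes = nrow(x$curve))
}

#' Extinction-curve plot
#'
#' @param object A `stability_report`.
#' @param ... Ignored.
#' @return A ggplot of `e(Delta)` with the interpolated `Delta_c` marked.
#' @export
autoplot.stability_report <- function(object, ...) {
  p <- ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$Delta, y = .data$e)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(Delta), y = "fraction with an extinction") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.na(object$delta_c)) {
    p <- p + ggplot2::geom_vline(xintercept = object$delta_c,
                                 linetype = 3, colour = "firebrick")
  }
  p
}

#' Predict structural stability from the effective system
#'
#' Solves `eta_v + Delta * eta_prime = eta_crit` per guild for the predicted
#' critical perturbation. For mutualism obligatory for animals, the plant
#' threshold is lowered by the minimum-plant-abundance requirement of
#' sole-partner plants: the equation becomes
#' `eta_v + Delta eta_prime = eta_crit (1 - phi (N_min(Delta)/<N_P> - 1))`
#' with the linear `N_min` model of [obligatory_min_abundance()] (the excess
#' abundance demanded beyond the unperturbed equilibrium), which amounts to an
#' extra slope `phi * eta_crit * d(N_min/<N_P>)/dDelta`. The overall
#' prediction is the minimum over guilds.
#'
#' @param sys An [effective_system()].
#' @param line The [eta_line()] tibble for `sys` (computed if missing).
#' @param n_reps,seed Passed to [eta_line()] when `line` is missing.
#' @return Tibble with one row per guild plus an `"overall"` row: `delta_c`
#'   (`<= 0` reported as is when `eta_v >= eta_crit`: structurally unstable at
#'   `Delta = 0`), and `defined` (`FALSE` when `eta_prime <= 0`).
#' @export
predict_delta_c <- function(sys, line = NULL, n_reps = 100, seed = NULL) {
  line <- line %||% eta_line(sys, n_reps = n_reps, seed = seed)
  obl <- obligatory_min_abundance(sys)
  per_guild <- function(guild) {
    l <- line[line$guild == guild, ]
    ec <- sys[[guild]]$eta_crit
    slope_extra <- if (guild == "plants") obl$phi * ec * obl$slope else 0
    denom <- l$eta_prime + slope_extra
    if (denom <= 0) {
      return(tibble::tibble(guild = guild, delta_c = NA_real_,
                            defined = FALSE, eta_crit = ec,
                            eta_v = l$eta_v, eta_prime = l$eta_prime))
    }
    tibble::tibble(guild = guild, delta_c = (ec - l$eta_v) / denom,
                   defined = TRUE, eta_crit = ec, eta_v = l$eta_v,
                   eta_prime = l$eta_prime)
  }
  out <- dplyr::bind_rows(per_guild("plants"), per_guild("animals"))
  overall <- if (all(out$defined)) min(out$delta_c) else NA_real_
  dplyr::bind_rows(out, tibble::tibble(
    guild = "overall", delta_c = overall, defined = all(out$defined),
    eta_crit = NA_real_, eta_v = NA_real_, eta_prime = NA_real_))
}
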