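#' Simulation regime presets
#'
#' The eight studied meta-parameter regimes: facultative or obligatory (for
#' animals) mutualism, weak or strong mutualistic saturation, and weak
#' (`rho = 0.05`) or strong (`rho = 0.23`) direct competition.
#'
#' * A: facultative, weak mutualism (saturation scale 0.1), rho = 0.05
#' * B: facultative, strong mutualism (saturation 100x weak = 10), rho = 0.05
#' * C: facultative, weak mutualism, rho = 0.23
#' * D: facultative, strong mutualism, rho = 0.23
#' * E/F: obligatory for animals, gamma0 = 0.1, rho = 0.05 / 0.23
#' * G/H: obligatory for animals, gamma0 = 0.3, rho = 0.05 / 0.23
#'
#' The weak-regime saturation scale is set to 0.1 (maximum mutualistic growth
#' rate 10, about three times the equilibrium competition load) so that
#' facultative equilibria destabilize at finite mutualism strength — the
#' defining phenomenology of the facultative regimes, and the reason a
#' stable-range `gamma0` policy exists at all; the strong regimes multiply
#' this scale by 100.
#'
#' Facultative presets choose `gamma0` at run time as `gamma_frac` of the
#' smallest lower stability boundary across the network ensemble (computations
#' are only performed at mutualism strengths dynamically stable for every
#' network); obligatory presets fix `gamma0` directly (their equilibria are
#' stable at all `gamma0`).
#'
#' @param label One of `"A"`-`"H"`.
#' @return List with `label`, `meta` ([meta_parameters()]), `gamma_frac`
#'   (fraction of the ensemble-wide stable range; `NA` for obligatory) and
#'   `description`.
#' @export
regime_preset <- function(label = c("A", "B", "C", "D", "E", "F", "G", "H")) {
  label <- match.arg(label)
  spec <- list(
    A = list(rho = 0.05, sat = 0.1, mut = "facultative", g0 = NA, frac = 0.5),
    B = list(rho = 0.05, sat = 10, mut = "facultative", g0 = 0.3, frac = 0.5),
    C = list(rho = 0.23, sat = 0.1, mut = "facultative", g0 = NA, frac = 0.5),
    D = list(rho = 0.23, sat = 10, mut = "facultative", g0 = 0.3, frac = 0.5),
    E = list(rho = 0.05, sat = 1, mut = "obligatory_animals", g0 = 0.1, frac = NA),
    F = list(rho = 0.23, sat = 1, mut = "obligatory_animals", g0 = 0.1, frac = NA),
    G = list(rho = 0.05, sat = 1, mut = "obligatory_animals", g0 = 0.3, frac = NA),
    H = list(rho = 0.23, sat = 1, mut = "obligatory_animals", g0 = 0.3, frac = NA)
  )[[label]]
  meta <- meta_parameters(rho_P = spec$rho, rho_A = spec$rho,
                          gamma0 = if (is.na(spec$g0)) 0.1 else spec$g0,
                          sat_P = spec$sat, sat_A = spec$sat,
                          mutualism = spec$mut)
  list(label = label, meta = meta, gamma_frac = spec$frac,
       description = sprintf("%s mutualism, saturation %g, rho = %g",
                             spec$mut, spec$sat, spec$rho))
}

#' Generate a network ensemble with controlled connectance and nestedness
#'
#' Crosses connectance multipliers `f` (via [sample_network()] from the
#' reference degree sequences) with nestedness offsets (via
#' [tune_nestedness()] towards the sampled network's value plus the offset).
#'
#' @param degrees List with `deg_P`, `deg_A` (default [study_degrees()]).
#' @param f Connectance multipliers.
#' @param nu_offsets Target nestedness offsets relative to each sampled
#'   network's value.
#' @param seed Integer seed.
#' @param max_swaps,tolerance Passed to [tune_nestedness()].
#' @return Tibble with columns `id`, `f`, `nu_target`, `network`
#'   (list-column), `kappa`, `nu`, `swaps`, `converged`.
#' @export
generate_ensemble <- function(degrees = study_degrees(),
                              f = c(0.7, 1, 1.6, 2.6),
                              nu_offsets = c(-0.03, 0, 0.04, 0.08, 0.12),
                              seed = 1L, max_swaps = 30000L,
                              tolerance = 0.01) {
  grid <- expand.grid(f = f, off = nu_offsets)
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    s <- child_seed(seed, i)
    net <- sample_network(degrees$deg_P, degrees$deg_A, f = grid$f[i], seed = s)
    target <- min(max(nestedness(net, "both") + grid$off[i], 0.01), 0.99)
    tuned <- suppressWarnings(
      tune_nestedness(net, target, max_swaps = max_swaps,
                      tolerance = tolerance, seed = child_seed(s, 1)))
    tibble::tibble(id = i, f = grid$f[i], nu_target = target,
                   network = list(tuned), kappa = connectance(tuned),
                   nu = nestedness(tuned, "both"),
                   swaps = attr(tuned, "swaps"),
                   converged = attr(tuned, "converged"))
  })
  dplyr::bind_rows(rows)
}

# smallest lower stability boundary of gamma0 across an ensemble
ensemble_gamma_range <- function(networks, meta, seed = 1L,
                                 grid = 10^seq(-2, 1, length.out = 12)) {
  mins <- vapply(seq_along(networks), function(i) {
    br <- critical_gamma_bracket(networks[[i]], meta,
                                 seed = child_seed(seed, i), grid = grid,
                                 tol = 1e-3)
    if (br$all_stable) Inf else br$gamma_minus
  }, numeric(1))
  min(mins)
}

#' Run the four-step structural-stability protocol over an ensemble
#'
#' For each network: (1) draw abundances and interactions and solve the
#' feasible equilibrium, (2) verify dynamical stability at the working
#' mutualism strength, (3) reduce to the effective competition systems and fit
#' the perturbation-response line, (4) measure the critical perturbation by
#' Monte-Carlo integration and predict it from `(eta_crit, eta_v, eta_prime)`.
#' Failures are recorded per network/realization and do not abort the run.
#'
#' @param networks List of [bipartite_network()] objects (or an ensemble
#'   tibble from [generate_ensemble()]).
#' @param preset A [regime_preset()] (or its label).
#' @param seed Integer seed.
#' @param n_real Realizations of the coefficient draws per network.
#' @param n_pert Perturbation replicates per amplitude.
#' @param delta_grid Amplitude grid for [measure_delta_c()].
#' @param n_reps_line Realizations for [eta_line()].
#' @param gamma0 Working mutualism strength; `NULL` applies the preset policy.
#' @param measure Run the Monte-Carlo measurement (set `FALSE` for an
#'   analytics-only pass)?
#' @return Tibble with one row per network x realization: descriptors,
#'   `rho_eff_*`, `eta_crit_*`, `eta_v_*`, `eta_prime_*`, `delta_c_pred`,
#'   `delta_c_meas`, `censored`, `gamma0`, `error`.
#' @export
run_protocol <- function(networks, preset = regime_preset("A"), seed = 1L,
                         n_real = 10, n_pert = 50,
                         delta_grid = seq(0.05, 0.8, by = 0.075),
                         n_reps_line = 50, gamma0 = NULL, measure = TRUE) {
  if (is.character(preset)) preset <- regime_preset(preset)
  if (tibble::is_tibble(networks)) networks <- networks$network
  meta <- preset$meta
  if (is.null(gamma0)) {
    if (meta$mutualism == "facultative") {
      g_min <- ensemble_gamma_range(networks, meta, seed = seed)
      gamma0 <- if (is.finite(g_min)) preset$gamma_frac * g_min else meta$gamma0
    } else {
      gamma0 <- meta$gamma0
    }
  }
  meta$gamma0 <- gamma0

  grid <- expand.grid(net = seq_along(networks), real = seq_len(n_real))
  rows <- purrr::map(seq_len(nrow(grid)), function(g) {
    i <- grid$net[g]; j <- grid$real[g]
    s <- child_seed(child_seed(seed, i), j)
    net <- networks[[i]]
    base <- tibble::tibble(network = i, realization = j,
                           kappa = connectance(net),
                           nu = nestedness(net, "both"), gamma0 = gamma0)
    tryCatch({
      comm <- build_community(net, meta, seed = s)
      stab <- local_stability(comm)
      if (!stab$stable) stop("equilibrium not locally stable at working gamma0")
      sys <- effective_system(comm)
      line <- eta_line(sys, n_reps = n_reps_line, seed = child_seed(s, 91))
      pred <- predict_delta_c(sys, line = line)
      meas <- if (measure) {
        measure_delta_c(comm, delta_grid = delta_grid, n_pert = n_pert,
                        seed = child_seed(s, 17))
      } else NULL
      dplyr::bind_cols(base, tibble::tibble(
        rho_eff_P = sys$plants$rho_eff, rho_eff_A = sys$animals$rho_eff,
        eta_crit_P = sys$plants$eta_crit, eta_crit_A = sys$animals$eta_crit,
        eta_v_P = line$eta_v[line$guild == "plants"],
        eta_v_A = line$eta_v[line$guild == "animals"],
        eta_prime_P = line$eta_prime[line$guild == "plants"],
        eta_prime_A = line$eta_prime[line$guild == "animals"],
        delta_c_pred = pred$delta_c[pred$guild == "overall"],
        delta_c_meas = if (measure) meas$delta_c else NA_real_,
        censored = if (measure) meas$censored else NA_character_,
        error = NA_character_))
    }, error = function(e) {
      dplyr::bind_cols(base, tibble::tibble(
        rho_eff_P = NA_real_, rho_eff_A = NA_real_,
        eta_crit_P = NA_real_, eta_crit_A = NA_real_,
        eta_v_P = NA_real_, eta_v_A = NA_real_,
        eta_prime_P = NA_real_, eta_prime_A = NA_real_,
        delta_c_pred = NA_real_, delta_c_meas = NA_real_,
        censored = NA_character_, error = conditionMessage(e)))
    })
  })
  dplyr::bind_rows(rows)
}

#' Deterministic fixture communities
#'
#' Small, seeded networks and one assembled community per regime label, used
#' by the test suite and reproducible bit-identically under the same seed.
#'
#' @param seed Integer seed.
#' @return List with `networks` (2x2 fully connected, 3x3 chain-nested, 5x7
#'   random) and `communities` (one per regime label A-H on an 8x8 random
#'   network).
#' @export
make_fixtures <- function(seed = 2024L) {
  nets <- list(
    full2 = bipartite_network(matrix(1, 2, 2)),
    nested3 = bipartite_network(matrix(c(1, 1, 1, 1, 1, 0, 1, 0, 0), 3, 3,
                                       byrow = TRUE)),
    rand57 = sample_network(rep(3L, 5), c(3L, 3L, 3L, 2L, 2L, 1L, 1L),
                            f = 1, seed = child_seed(seed, 1))
  )
  base <- random_bipartite(8, 8, 0.4, seed = child_seed(seed, 2))
  communities <- lapply(stats::setNames(LETTERS[1:8], LETTERS[1:8]),
                        function(lab) {
    preset <- regime_preset(lab)
    meta <- preset$meta
    if (meta$mutualism == "facultative") meta$gamma0 <- 0.05
    build_community(base, meta, seed = child_seed(seed, 3))
  })
  list(networks = nets, communities = communities)
}

#' Analytics summary of the fixture communities
#'
#' One row per regime label with the spectral summaries of the fixture
#' community; regenerating under the pinned seed must reproduce the golden
#' copy shipped in `inst/extdata/fixture_analytics.csv`.
#'
#' @param fixtures Output of [make_fixtures()].
#' @return Tibble with `label`, `rho_eff_P`, `rho_eff_A`, `eta_crit_P`,
#'   `eta_crit_A`, `eta_max_P`, `eta_max_A`.
#' @export
fixture_analytics <- function(fixtures = make_fixtures()) {
  rows <- purrr::imap(fixtures$communities, function(comm, lab) {
    sys <- effective_system(comm)
    tibble::tibble(label = lab,
                   rho_eff_P = sys$plants$rho_eff,
                   rho_eff_A = sys$animals$rho_eff,
                   eta_crit_P = sys$plants$eta_crit,
                   eta_crit_A = sys$animals$eta_crit,
                   eta_max_P = sys$plants$eta_max,
                   eta_max_A = sys$animals$eta_max)
  })
  dplyr::bind_rows(rows)
}
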