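Package: mutualstab
Title: Structural Stability of Mutualistic Communities via Effective Competition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the structural stability of bipartite mutualistic
    communities (plant-pollinator networks) governed by Lotka-Volterra dynamics
    with a saturating (Holling type II) mutualistic functional response.
    Generates bipartite networks with controlled connectance and nestedness
    (degree-preserving checkerboard swaps under a Metropolis criterion),
    assembles feasible model communities, linearizes them into an equivalent
    Lotka-Volterra system, reduces the two-guild system to per-guild effective
    competition matrices, and predicts the maximal tolerable environmental
    perturbation from three spectral summaries: the effective interspecific
    competition, the propagation of perturbations, and the unperturbed
    vulnerability. Includes Monte-Carlo measurement of structural stability by
    adaptive ODE integration, closed forms and numerical roots for the critical
    direct competition at which mutualism stops reducing effective competition,
    and Z-scores against connectance-matched random networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
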