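# mutualstab

Structural stability of mutualistic communities through effective
competition.

Plant–pollinator communities are commonly modelled as two guilds of
Lotka–Volterra competitors coupled by a saturating (Holling type II)
mutualistic response:

$$\frac{1}{N_i}\frac{dN_i}{dt} = \alpha_i - \sum_j \beta_{ij} N_j
+ \frac{1}{h_i}\frac{z_i}{1+z_i}, \qquad
z_i = h_i \sum_k \gamma_{ik} N_k .$$

Whether the mutualistic network helps or harms coexistence in this model is
not a single-signed question. This package implements the analysis chain
that answers it quantitatively:

* **Networks** — build, read and write binary plant × animal incidence
  matrices; connectance, degree moments and the shared-partner nestedness;
  a generator with controlled connectance (degree-sequence sampling) and
  nestedness (degree-preserving checkerboard swaps under a Metropolis
  criterion).
* **Communities** — assemble feasible model communities: equilibrium
  abundances are drawn, intrinsic growth rates are solved from the fixed
  point, facultative and obligatory (animal) mutualism regimes included.
* **Linearization** — the equivalent Lotka–Volterra system at equilibrium
  ($\gamma^{LV} = \gamma/(1+z)^2$), local stability from the community
  matrix, a tri-state diagonal-stability certificate, and bracketing of the
  critical mutualistic strengths $\gamma_0^\pm$.
* **Effective competition** — eliminate one guild:
  $C = \beta - \gamma^{LV}\beta_{\text{other}}^{-1}\gamma^{LV}_{\text{other}}$;
  spectral summaries $\rho^{\text{eff}}$, $S^{\text{eff}}$, the feasibility
  threshold $\eta^c = S^{\text{eff}}/(S^{\text{eff}}+S)$ and per-species
  vulnerabilities $\eta_i$.
* **Structural stability** — measured: Monte-Carlo growth-rate perturbations
  of amplitude $\Delta$ integrated with a compiled adaptive Dormand–Prince
  scheme until equilibrium or extinction, $\Delta_c$ at the 50%-extinction
  crossing; predicted: $\Delta_c = (\eta^c - \eta_v)/\eta'$ per guild from
  the perturbation-response line, with an obligatory-mutualism correction.
* **Critical competition** — the direct-competition level $\rho^c$ below
  which mutualism reduces effective competition: regime closed forms
  (weak / strong / weak–strong), a regime-free numerical root, the
  two-guild fixed point, and Z-scores against connectance-matched random
  networks.

Results come back as tibbles; fitted objects have `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

```r
library(mutualstab)

deg <- study_degrees()                       # 47 x 46, ~151 links
net <- sample_network(deg$deg_P, deg$deg_A, f = 1, seed = 11)
glance(net)[, c("connectance", "nestedness")]
#> # A tibble: 1 × 2
#>   connectance nestedness
#>         <dbl>      <dbl>
#> 1      0.0703      0.225

comm <- build_community(net, meta_parameters(rho_P = 0.05, rho_A = 0.05,
                                             gamma0 = 0.1), seed = 7)
sys <- effective_system(comm)
sys
#> <effective_system> rho_eff: plants 0.0501, animals 0.0502 | eta_crit: 0.2872, 0.2915 | eta_max: 0.0416, 0.0406

predict_delta_c(sys, n_reps = 50, seed = 3)
#> # A tibble: 3 × 6
#>   guild   delta_c defined eta_crit   eta_v eta_prime
#>   <chr>     <dbl> <lgl>      <dbl>   <dbl>     <dbl>
#> 1 plants    0.306 TRUE       0.287  0.0198     0.873
#> 2 animals   0.302 TRUE       0.292  0.0269     0.875
#> 3 overall   0.302 TRUE      NA     NA         NA

measure_delta_c(comm, delta_grid = seq(0.1, 1.2, by = 0.1),
                n_pert = 50, seed = 9)
#> <stability_report> Delta_c = 0.2875 (none), 50 perturbations x 14 amplitudes
```

The effective interspecific competition barely moves from the direct value
(0.050), the feasibility threshold is ≈ 0.29, and the community tolerates
relative growth-rate perturbations of about ±0.29–0.30 before half the
perturbed replicates lose a species — measured (0.2875) and predicted
(0.302) agree to a few percent here.

Critical competition of the same network:

```r
rho_crit_fixed_point(net, gamma0 = 0.05)
#> # A tibble: 1 × 6
#>   rho_c_P rho_c_A iterations converged censored_P censored_A
#>     <dbl>   <dbl>      <int> <lgl>     <chr>      <chr>
#> 1  0.0893   0.116         16 TRUE      none       none
```

Direct competition below ≈ 0.09 (plants): mutualism lowers effective
competition on this network; above it, mutualism raises it.

A thin command-line wrapper for the shell workflows (describe / sample /
tune / critcomp / measure) ships in `inst/cli/mutualstab.R`.

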