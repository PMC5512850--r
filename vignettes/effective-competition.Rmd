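---
title: "Effective competition and the structural stability of mutualistic communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective competition and the structural stability of mutualistic communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`mutualstab` studies communities of $S^{(P)}$ plants and $S^{(A)}$ animals
(pollinators, seed dispersers) linked by a binary bipartite network
$a_{ik}$. Within each guild species compete; across guilds linked pairs help
each other, with diminishing returns. In rescaled units (intraspecific
competition 1, guild-mean abundances 1) the per-capita growth rate of plant
$i$ is

$$\frac{1}{N_i}\frac{dN_i}{dt} \;=\; \alpha_i \;-\; \sum_j \beta_{ij} N_j
\;+\; \frac{1}{h_i}\,\frac{z_i}{1+z_i},
\qquad z_i = h_i \sum_k \gamma_{ik} N_k,$$

and symmetrically for animals. The mutualistic term is a Holling type II
(saturating) functional response: $1/h_i$ is the maximum mutualistic growth
rate and $z_i$ the dimensionless saturation factor at the current state. The
animal equations mirror the plant ones with superscripts exchanged.

Competition is fully connected, $\beta_{ij} = \rho\, b_{ij}$ off-diagonal
with $b_{ij}$ uniform on $[1-\delta_b, 1+\delta_b]$, so a single
meta-parameter $\rho < 1$ per guild sets the interspecific-to-intraspecific
ratio. Mutualistic strengths are $\gamma_{ik} = \gamma_0\, c_{ik} a_{ik}$
(uniform $c$ on $[1-\delta_c, 1+\delta_c]$), scaled by
$\sqrt{\bar N^{(A)}/\bar N^{(P)}}$ on the plant side and its inverse on the
animal side, so that a large plant-to-animal abundance ratio pushes animals —
and only animals — toward saturation. Facultative mutualism uses ratio 1.

Communities are assembled *feasibly by construction*: equilibrium abundances
$N^*_i$ are drawn first (uniform on $[1 \pm \delta_N]$, $\delta_N = 0.15$, or
log-normal), and the intrinsic growth rates $\alpha_i$ are solved from the
fixed-point condition. The residual of the fixed point is checked against
$10^{-10}$ on every assembly. Two consequences worth knowing: the solved
$\alpha_i$ are negatively rank-correlated with mutualistic degree (a
number-versus-strength trade-off), and with mutualism switched off they are
exchangeable across species.

Obligatory mutualism for animals ($\alpha^{(A)} < 0$) arises when the
abundance ratio $\bar N^{(P)}/\bar N^{(A)}$ and the maximum animal
mutualistic growth rate are large. `obligatory_abundance_bound()` evaluates
the closed-form requirement; at $S^{(A)} = 50$, $\rho^{(A)} = 0.25$,
$\gamma_0 = 0.1$ and minimum degree 1 it gives $\approx 2.8\times 10^5$, and
the package default ratio $10^6$ clears it with margin. The animal handling
scale is then pinned slightly below its feasibility ceiling,
$h_A = 0.75/(S_A\rho_A + 1 - \rho_A)$, with $h_P = 0.25$.

## From dynamics to effective competition

Every analysis step is a function with an object in and an object out:

```{r pipeline}
library(mutualstab)
net  <- sample_network(study_degrees()$deg_P, study_degrees()$deg_A,
                       f = 1, seed = 1)
comm <- build_community(net, regime_preset("A")$meta, seed = 1)
lv   <- equivalent_lv(comm)        # linearization at the equilibrium
sys  <- effective_system(lv)       # per-guild reduction
```

*Linearization.* At the fixed point the saturating model is equivalent to a
Lotka–Volterra system with effective couplings
$\gamma^{LV}_{ik} = \gamma_{ik}/(1+z_i)^2$ and growth-rate offsets
$m_i = (1/h_i)\,(z_i/(1+z_i))^2$. The equivalence is exact to first order:
the LV system shares the fixed point and the Jacobian, which the test suite
verifies against central differences of the full model. Local stability is
the spectrum of the community matrix $J = \mathrm{diag}(N^*) A$; global
stability is certified (when possible) through diagonal stability of $A$,
with an honestly tri-state verdict since the full problem is a linear matrix
inequality we do not solve.

*Guild reduction.* Eliminating animals from the linearized equilibrium gives
$C^{(P)} n^{(P)} = p^{(P)}$ with effective competition
$C^{(P)} = \beta^{(P)} - \gamma^{LV(P)} (\beta^{(A)})^{-1} \gamma^{LV(A)}$
and productivity
$p^{(P)} = \alpha^{LV(P)} + \gamma^{LV(P)} (\beta^{(A)})^{-1} \alpha^{LV(A)}$.
Shared mutualistic partners act like a *negative* indirect competition term.
Matrices are reported in units of unit effective intraspecific competition
(diagonal similarity), and the equilibrium identity is re-verified to
$10^{-8}$.

*Spectral summaries.* With $\lambda_1$ the leading eigenvalue and
$\bar\lambda_m$ the mean of the rest,
$\rho^{\mathrm{eff}} = (\lambda_1 - \bar\lambda_m)/(\lambda_1 +
(S-1)\bar\lambda_m)$ — the exact inversion of the mean-field spectrum, equal
to $(\lambda_1 - 1)/(S - 1)$ once $C_{ii} = 1$. The vulnerability of species
$i$ under productivity $p$ is $\eta_i = 1 - p_i/(p^1 v^1_i)$ with $v^1$ the
unit-norm Perron eigenvector and $p^1 = \langle p, v^1\rangle$; its
$(v^1_i)^2$-weighted mean is identically zero. Feasibility is guaranteed when
$\max_i \eta_i \le \eta^c = S^{\mathrm{eff}}/(S^{\mathrm{eff}} + S)$,
$S^{\mathrm{eff}} = (1-\rho^{\mathrm{eff}})/\rho^{\mathrm{eff}}$; with a
viability floor $n_c$ the bound tightens to $\eta^c (1 - n_c/\bar n)$
(exact in mean field). The sufficiency of this condition, and its near
necessity under random perturbations, are properties the suite tests by brute
force on thousands of small systems rather than assumes. The brute force also
delimits the guarantee honestly: away from mean field both sides of the
threshold equivalence shift by the off-diagonal heterogeneity scale, so
verdicts can break — rarely, and only within a thin band at the threshold
(at ±15% heterogeneity, about 1% of feasible verdicts, none with margin
above 0.05); the reduced effective systems this framework actually produces
never violated it in testing.

## Structural stability

A perturbation of amplitude $\Delta$ multiplies every growth rate by
$(1 + \Delta r_i)$, $r_i$ uniform on $[-1, 1]$. Measured structural
stability integrates the full dynamics for each perturbed replicate and finds
the amplitude $\Delta_c$ at which half the replicates lose at least one
species; predicted structural stability solves
$\eta_v + \Delta\,\eta' = \eta^c$ per guild, where the unperturbed
vulnerability $\eta_v$ and the propagation of perturbations $\eta'$ come from
a two-point finite difference of the mean maximal vulnerability at probe
amplitudes $\eta^c \pm 0.05$ (shifted, with a warning, when
$\eta^c \le 0.05$). The overall prediction is the minimum over guilds. For
obligatory mutualism the plant equation acquires an extra slope
$\phi\,\eta^c\, \mathrm{d}(N_{\min}/\langle N^{(P)}\rangle)/\mathrm{d}\Delta$:
$\phi$ counts plants that are the sole diet of some animal, and
$N_{\min}(\Delta)$ is the plant abundance that keeps such an animal's
perturbed growth non-negative, linearized about the equilibrium with the
saturation-dominant terms kept.

An analytic estimate of $\eta'$ propagates perturbation variances through
$G = \gamma^{LV(P)}(\beta^{(A)})^{-1}$ and carries one undetermined
multiplicative constant. The constant was calibrated once against the
numeric slope on a 20-network facultative weak-mutualism reference ensemble
at study scale: the median ratio was 1.56 (spread 1.47–1.58 across networks),
frozen in `eta_prime_constant()`. The estimate is advisory — the numeric
slope is authoritative — but it carries the two qualitative lessons: more
links damp propagation (root-sum-square over $d_i + 1$ positive terms against
their plain sum), and obligatory mutualism amplifies it (opposite signs of
$\alpha$ and $m$ shrink the denominator).

## Critical competition

Mutualism reduces effective competition only below a critical direct
competition $\rho^c$. The package computes it three ways, and their
agreement is itself a test:

1. **Closed forms per regime** (`rho_crit_closed_form()`): first-order
   perturbation theory of $C$ under the mean-field inverse of the other
   guild's competition matrix. The weak form (all $z \ll 1$) uses couplings
   $\propto a_{ik}$; the strong form (all $z \gg 1$) couplings
   $\propto a_{ik}/d_i^2$; the obligatory weak–strong form mixes them, and
   its coupling product is independent of $\gamma_0$, with magnitude
   suppressed by the abundance ratio — mutualism then barely moves
   $\rho^{\mathrm{eff}}$. Fully connected networks give $\rho^c = 1$ exactly
   in the weak and strong forms; at full connectance and small $\gamma_0$ the
   effective competition follows
   $\rho^{\mathrm{eff}} = \rho - \gamma_0^2 (1-\rho) F^{(A)}/\rho^{(A)}$ with
   $F = \rho S/(\rho S + 1 - \rho)$, which the suite verifies to fourth order
   in $\gamma_0$.
2. **A regime-free numerical root** (`rho_crit_numeric()`): the fixed point
   of $\rho \mapsto \rho^{\mathrm{eff}}(\rho)$ through the full pipeline,
   with censoring flags instead of clipped values when no root lies in
   $(0,1)$.
3. **The two-guild fixed point** (`rho_crit_fixed_point()`): alternating the
   per-guild closed forms to convergence; the result is independent of the
   initialization to $10^{-8}$.

A structural fact the implementation surfaced: the weak closed form depends
on the network only through $L$, $\sum_i d_i^2$ (both guilds) and the guild
sizes. It is therefore *invariant under degree-preserving rewiring* —
nestedness influences it only across degree sequences, through the
degree-heterogeneity ratio $\langle d^2\rangle/\langle d\rangle$ that
nestedness tracks. The rewiring-level nestedness dependence is real but
lives in the exact spectral route, which the tests probe separately.
Z-scores (`rho_crit_zscore()`) compare a network's $\rho^c$ with uniform
random bipartite networks at matched size and connectance; degree-preserving
nulls are deliberately not used, since they would freeze most of what is
being measured.

## The synthetic network generator

Networks are sampled from target degree sequences: link $(i,k)$ appears with
probability $\min(1, f\, d_i d_k / L)$, so $f = 1$ reproduces the template's
expected degrees and $f$ scales connectance. The shipped template
(`study_degrees()`) is a deterministic truncated-power-law-like rank profile
at the scale of a field pollination web: 47 plants, 46 animals, 151 links,
connectance $\approx 0.07$, minimum degree 1. Species left unlinked by a
draw are repaired by redrawing only their own row or column (whole-matrix
rejection cannot terminate at this sparsity, where each degree-1 species is
empty with probability $\sim e^{-1}$).

Nestedness here is the pairwise shared-partner measure: the mean over
same-guild pairs of $n_{ij}/\min(d_i, d_j)$. The ratio-of-sums variant
$\sum n_{ij} / \sum \min(d_i,d_j)$ is fully determined by the two degree
sequences (its numerator is $(\sum_k d_k^2 - L)/2$ over the opposite guild)
and therefore cannot be tuned at fixed degrees; the pair-averaged form can,
which is what makes a degree-preserving Metropolis tuner meaningful.
`tune_nestedness()` proposes checkerboard swaps — two links exchanged so
that all four degrees are conserved — and accepts a move whenever it reduces
$|\nu - \nu^\ast|$, otherwise with probability
$e^{-\Delta\mathrm{cost}/T}$, $T = 10^{-3}$, stopping inside a tolerance of
0.01. At study scale convergence to targets $\pm 0.05$ away typically takes
a few hundred proposals, far below the $2\times 10^4$ budget.

What the generator does *not* emulate: quantitative visit weights,
phenological turnover, sampling effort biases, and the degree–abundance
correlations of real webs. Passing tests therefore establish correctness of
the machinery on networks with realistic size, sparsity and heterogeneity,
not ecological verisimilitude of any particular web.

## Regime presets and working parameters

The eight presets (`regime_preset()`) cross facultative/obligatory mutualism,
weak/strong saturation and weak/strong direct competition
($\rho = 0.05 / 0.23$). Two numerical choices deserve their rationale:

* **Weak-regime saturation scale 0.1.** The saturation meta-parameter of the
  weak facultative regimes is set so that the maximum mutualistic growth
  rate $1/h = 10$ is about three times the equilibrium competition load.
  With a scale of 1 the mutualistic gain is capped below the competition
  load and no facultative equilibrium can ever destabilize — yet the
  existence of a finite instability window $(\gamma_0^-, \gamma_0^+)$ is the
  defining phenomenology of facultative mutualism in this model, and the
  working-$\gamma_0$ policy ("half of the ensemble-wide stable range") is
  meaningless without it. Strong regimes multiply the weak scale by 100.
  At study scale this puts $\gamma_0^-$ near 0.4 at $\rho = 0.05$.
* **Desk-scale experiment sizes.** The default protocol runs 12–20 networks
  × 2 realizations × 30–50 perturbation replicates per amplitude, with
  adaptive refinement of the amplitude grid around the $e = 0.5$ crossing.
  These sizes keep a full two-regime comparison within minutes on one core
  while leaving the Monte-Carlo standard error of $\Delta_c$ an order of
  magnitude below the across-network spread it must resolve.

## Numerical choices

* **Integration.** A compiled adaptive Dormand–Prince 5(4) integrator with
  extinction clamping in the inner loop: a species falling below $10^{-8}$
  of its initial abundance is extinct and frozen at zero (an absorbing
  state; re-equilibration of the survivors continues). Local tolerances
  `rtol = 1e-8`, `atol = 1e-10`; the absolute tolerance sits deliberately
  between the extinction threshold and machine precision — tightening it
  far below the threshold forces vanishing steps while species decay toward
  extinction.
* **Equilibrium detection.** Integration stops when the largest per-capita
  growth rate among extant species falls below $10^{-6}$. The criterion is
  deliberately about two orders of magnitude above the integrator's accuracy
  floor (the numerical state hovers at distance $\sim$`rtol` from the true
  equilibrium, so measured rates cannot fall below it) and five below
  typical dynamical rates. Extinction-bound species keep a run alive
  automatically: their rates stay of order $|\alpha|$ until they cross the
  threshold.
* **Common random numbers.** Perturbation replicates are keyed by replicate
  index, so different amplitudes share perturbation directions. Extinction
  curves are then monotone up to integration effects and finite-difference
  slopes across amplitudes are nearly noise-free; the cost is a (harmless)
  correlation between points of the same curve.
* **Interpolation and censoring.** $\Delta_c$ is the linear interpolation of
  the $e = 0.5$ crossing between bracketing grid points, refined twice;
  when the curve never crosses, a censored verdict is returned rather than
  an extrapolated number. The same philosophy applies to $\rho^c$ outside
  $(0,1)$: explicit flags, never clipped values.
* **Eigenpairs.** Dense eigendecomposition; the right eigenvector of the
  largest-real-part eigenvalue, sign-fixed positive. A non-positive leading
  eigenvector or a complex leading pair marks the system degenerate instead
  of silently proceeding.

## Known limitations

* The "connectance raises $\rho^{\mathrm{eff}}$ above $\rho^c$" direction is
  a weak-limit statement. At working parameters strong enough to measure,
  hub species saturate first, and since the quadratic network terms are
  $d^2$-weighted, exactly the hub contributions attenuate; the trend then
  flattens or reverses at this package's degree heterogeneity. The property
  is verified far from saturation, where both directions of the flip are
  clean.
* Predation (sign-flipped cross-guild interactions) has algebraic hooks in
  the reduction but is untested and unsupported.
* The diagonal-stability certificate is sufficient-only by design;
  `inconclusive` is a common and honest answer for strongly coupled systems.
* The analytic $\eta'$ estimate shares its calibration constant across
  regimes; it is meant for ranking networks, not for absolute prediction.
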