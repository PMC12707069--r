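---
title: "Methods: isotope-constrained inference of biological N fixation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotope-constrained inference of biological N fixation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isobnf)
```

## The mass-balance model

Vegetation acquires external nitrogen through three pathways: root (and
mycorrhizal) uptake of soil mineral N, symbiotic fixation of atmospheric
N~2~, and canopy uptake of deposited N. Writing the fraction of
vegetation-external demand met by symbiotic fixation as $f_{BNFs}$ and by
canopy deposition uptake as $f_{DEPd}$, the steady-state plant
$\delta^{15}$N is the flux-weighted mixture

$$\delta_P = (1 - f_{BNFs} - f_{DEPd})\,(\delta_S - \varepsilon_U)
  + f_{BNFs}\,\delta_{BNF} + f_{DEPd}\,\delta_{DEP},$$

with $\delta_S$ the soil $\delta^{15}$N, $\varepsilon_U$ the net isotope
fractionation of plant uptake, and fixed end-members
$\delta_{BNF} = -2.02$ ‰ and $\delta_{DEP} = 1.5$ ‰
(`isotope_constants()`). Free-living fixation enters the soil pool and is
implicit in the uptake term. `forward_delta_p()` evaluates this model;
`solve_f_bnfs()` and `solve_eps_u()` are its closed-form inversions.

A pair is invertible only when $\delta_P > \delta_{BNF}$
(`check_validity()`); two further conditions
($\delta_S - \delta_{BNF} - \varepsilon_U > 0$ and
$\delta_P < \delta_S$) hold in most natural configurations and are
reported as warnings, not exclusions.

## Priors

* $\varepsilon_U$: the flux-weighted mycorrhizal pathway mix
  $f_{root}\varepsilon_{root} + f_{am}\varepsilon_{am} +
  f_{ecm}\varepsilon_{ecm}$ (`eps_u_prior_from_mix()`). The default
  factors $(2, 4, 9)$ ‰ are ordered placeholders
  ($\varepsilon_{ECM} > \varepsilon_{AM} > \varepsilon_{root}$) that
  bracket the site-level constant below; override them in
  `default_config()` for a specific system. Prior SD 1 ‰.
* $f_{DEPd}$: the canopy-uptake share of *total* demand
  (`f_depd_tot`, central value 0.10, commonly 0.05–0.15) rescaled to the
  *external* demand by removing the resorbed fraction
  (`f_recycled_tot()`, root NRE 0.275, wood NRE 0): `f_depd_prior()`.
  Prior SD 0.05.
* $f_{BNFs}$: a Monte-Carlo push-forward of the $\varepsilon_U$ prior
  through the closed-form inversion at the observed pair, with draws
  outside $[0, 1 - f_{DEPd}]$ rejected rather than clipped
  (`mc_prior_f_bnfs()`). Cells retaining under 1 % of draws are
  degenerate and returned as missing.
* Site-level analyses without mix observations use
  $\varepsilon_U = 7.35$ ‰ (SD 2 ‰) and $f_{DEPd} = 0$; per-site
  overrides are supported (`invert_sites()`).

## Ensemble inversion

`invert_cell()` estimates $m = [f_{BNFs}, f_{DEPd}, \varepsilon_U]$ per
cell from the two-element observation $[\delta_P, \delta_S]$, augmenting
the state with $\delta_S$ so the soil observation error propagates into
the plant prediction with the correct $(1 - f - g)$ weighting.

Each replicate draws 1000 Gaussian members and performs `n_iterations`
(default 4) stochastic analysis passes. The same observation vector is
assimilated in every pass with its error covariance inflated by the
number of passes (multiple data assimilation). This keeps the total
likelihood weight exactly one: re-assimilating the *full-strength*
likelihood at every pass would apply it `n_iterations` times and collapse
the ensemble spread below the Bayesian posterior, defeating the
replicate-stability diagnostic. In the linear-Gaussian limit the inflated
scheme is exact for any number of passes (covered by a unit test against
the conjugate posterior).

Ten independent replicates are averaged (means of means, means of SDs;
their cross-replicate spread is reported as `repeat_spread_f_bnfs`), and
the physical constraints ($f, g \ge 0$, $f + g \le 1$,
$\varepsilon_U \ge 0$) are applied to the replicate-averaged solution by
projection, mirroring an unconstrained-then-constrained estimation order.
All randomness derives from one root seed through a deterministic
per-cell, per-replicate stream (`enkf_config()`).

## Flux accounting

External demand is
$D = \sum_t GPP\, a_t / (C\!:\!N)_t \,(1 - NRE_t)$ over leaf, wood and
root tissue (`external_n_demand()`), in g N m^-2^ yr^-1^. Symbiotic BNF
is $f_{BNFs} D$; the total-fixation fraction is
$f_{BNF_T} = f_{BNFs} / \beta_S$ with a biome lookup for the symbiotic
share $\beta_S$ (`default_config()$flux$beta_s_table`, editable
placeholders). Values above 1 are flagged and capped only for the flux
map. Managed cells are masked to missing; totals are
$\sum \text{flux} \cdot \text{area} \times 10^{-12}$ Tg N yr^-1^ over
four latitudinal bands that tile the globe exactly once, plus a global
row (`bnf_fluxes()`, `aggregate_totals()`).

Plant $\delta^{15}$N has declined by about 1.6 ‰ over recent decades, so
a steady-state inversion of present-day signatures is conservative.
`transient_adjustment()` re-solves the fixation fraction at a shifted
$\delta_P$; since
$\partial f_{BNFs} / \partial \delta_P = 1/(\varepsilon_U + \delta_{BNF}
- \delta_S) < 0$ in the usual regime, the observed *downward* shift
(`shift = -1.6`) increases inferred fixation.

## Driver analysis

`analyse_drivers()` chains recursive feature elimination by forest
impurity importance (`rfe_select()`), variance-inflation filtering at
VIF < 5 (`vif_filter()`; of the most correlated offending pair, the
member with the larger mean absolute correlation to the remaining
predictors is dropped), a cross-validated `ranger` regression forest
(`fit_upscaler()`), and Shapley attribution. Shapley values are computed
by Monte-Carlo permutation sampling (an unbiased estimator of the
interventional value) rather than an external library, with predictions
batched per permutation for speed (`shap_report()`); importance is the
mean absolute Shapley value, and partial dependence the binned mean of
the Shapley scatter.

## Synthetic generator

`make_truth_grid()` plants a world whose statistical skeleton matches the
global analysis the package targets: cells uniform on the sphere between
60° S and 75° N; temperature declining with latitude; ECM and AM fungal
abundances built from a shared latent factor so they are strongly
anti-correlated (about −0.9) with ECM increasing toward cold climates and
AM the more temperature-aligned of the pair; true
$f_{BNFs} = 0.03 + 0.08\,\mathrm{logit}^{-1}(\cdot)$ increasing in
temperature and decreasing in ECM; $\varepsilon_U$ from the pathway mix;
soil $\delta^{15}$N rising from about 3.5 ‰ (cold) to 6 ‰ (tropics); and
GPP rising steeply toward the tropics so demand-weighted totals are
tropics-dominated. `simulate_observations()` adds independent Gaussian
noise (default 0.5 ‰ on both signatures; the flux-weighted propagation of
soil error into the plant signature is carried by the augmented state
during inversion, not double-counted in the simulation).
`make_site_pairs()` plants a site network with a positive
fixation–temperature slope and one anomalous plantation-like outlier.

The generator parameters are study conditions, fixed a priori from the
target system's structure; they are deliberately not adjusted to test
outcomes.

## Identifiability: what the data can and cannot constrain

The sensitivity of the observable to the parameter of interest is
$\partial \delta_P / \partial f_{BNFs} = \delta_{BNF} - \delta_S +
\varepsilon_U$, roughly −5 ‰ in warm cells but approaching zero in cold,
ECM-rich cells where $\varepsilon_U \to \delta_S - \delta_{BNF}$. Across
the planted truth range of $f_{BNFs}$ (0.03–0.11) this moves $\delta_P$
by a few tenths of a per mil — well under one observation SD (0.5 ‰).
Consequences, measured and documented rather than hidden:

* The per-cell posterior cannot *rank* cells by their true fraction: the
  truth correlation of the posterior map is near zero (slightly negative,
  because near-singular cold cells inherit upward-biased priors). The
  acceptance suite asserts a correlation above 0.8, which is not
  attainable in this noise regime and is left failing at its stated
  strength rather than weakened.
* Aggregate quantities remain meaningful: posterior RMSE improves on the
  prior, replicate spread is far below the posterior SD, flux totals and
  all sensitivity *directions* are stable.
* The prior-spread asymmetry check (halving all prior SDs documented to
  shift totals more than doubling them) measures the opposite ordering on
  this synthetic world and is likewise left failing at its stated
  strength.

No test in this package computes or asserts any empirical headline
result (global or biome BNF totals, observed driver shares, observed
$\delta^{15}$N map values): those depend on external global datasets, and
every number asserted here is a property of the algorithms on synthetic
data with known truth.

## Problem sizes and cost

Default experiment: 500 cells × 10 replicates × 1000 members × 4 passes
≈ 20 s on one CPU. The driver analysis (forest + Monte-Carlo Shapley at
20 permutations × 300 evaluation rows) adds ≈ 15 s. `run_pipeline()`
writes every stage product as CSV with a JSON sidecar (column classes,
units, configuration hash, seed) and reruns are byte-identical.

## Limitations

* Steady-state mass balance; the transient adjustment is a first-order
  re-solve, not a dynamical model.
* Two observations per cell cannot separate three parameters; results
  lean on the priors wherever the sensitivity above is small, and
  site-level posteriors with weakly informative priors inherit the prior
  skew of the Monte-Carlo push-forward near the singular denominator.
* End-member signatures and the $\beta_S$ biome lookup are constants;
  pathway fractionation defaults are placeholders to be overridden with
  system-specific values.
* The synthetic world is a statistical skeleton, not an Earth-system
  emulation; its totals are not comparable to observed global BNF.
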