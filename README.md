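# isobnf

Isotope-constrained inference of biological nitrogen fixation (BNF).

## The scientific problem

Symbiotic fixation of atmospheric N<sub>2</sub> is a major but poorly
quantified input of nitrogen to land ecosystems. Because fixed N carries a
distinctive isotopic signature, the fraction of a plant's external N
demand met by fixation leaves a fingerprint in its δ¹⁵N. `isobnf` turns
paired plant and soil δ¹⁵N observations into per-cell estimates of that
fraction and into BNF fluxes, with honest uncertainties.

The steady-state mass balance at the core of the package is

```
δP = (1 − f_BNFs − f_DEPd) (δS − εU) + f_BNFs δ_BNF + f_DEPd δ_DEP
```

where `δP` and `δS` are plant and soil δ¹⁵N (‰), `f_BNFs` is the
symbiotic-fixation share of vegetation-external N demand, `f_DEPd` the
canopy-deposition share, `εU` the net fractionation of plant uptake, and
`δ_BNF = −2.02 ‰`, `δ_DEP = 1.5 ‰` are fixed end-members. The package
provides:

* closed-form inversions of this model (`solve_f_bnfs()`,
  `solve_eps_u()`) with validity checking;
* prior construction, including a Monte-Carlo prior for `f_BNFs`
  (`build_priors()`);
* a per-cell Bayesian update by an iterative ensemble Kalman filter with
  replicated ensembles and post-hoc physical constraints
  (`invert_grid()`, `invert_sites()`);
* flux accounting from fractions to Tg N yr⁻¹ globally and by
  latitudinal band, with a transient δ¹⁵N-decline adjustment
  (`bnf_fluxes()`, `transient_adjustment()`);
* a driver-analysis chain — recursive feature elimination, VIF
  filtering, random-forest upscaling, Shapley attribution
  (`analyse_drivers()`);
* a synthetic-data generator with known truth (`make_truth_grid()`,
  `simulate_observations()`, `make_site_pairs()`) so every stage is
  testable without external downloads;
* a reproducible pipeline writing CSV artifacts with JSON metadata
  sidecars and a manifest (`run_pipeline()`).

All functions take and return tibbles; results have `tidy()` / `glance()`
methods and `autoplot()` / `plot_*()` graphics.

## Worked example

```r
library(isobnf)
library(dplyr)

# closed-form model
forward_delta_p(f_bnfs = 0.08, f_depd = 0.05, eps_u = 4, delta_s = 5)
#> [1] 0.7834
solve_f_bnfs(delta_p = 0.5, delta_s = 5, eps_u = 4, f_depd = 0.05)
#> [1] 0.1738411

# synthetic world -> priors -> ensemble inversion
cfg <- default_config()
truth <- make_truth_grid(n_cells = 200, seed = 42)
grid  <- rename_truth(simulate_observations(truth, seed = 43))
priors <- build_priors(grid, cfg, seed = 44)
post <- invert_grid(priors, cfg$constants, cfg$inversion)
post |>
  select(lat, delta_p, delta_s, f_bnfs, f_bnfs_sd, eps_u, valid) |>
  print(n = 4)
#> # A tibble: 200 × 7
#>     lat delta_p delta_s f_bnfs f_bnfs_sd eps_u valid
#>   <dbl>   <dbl>   <dbl>  <dbl>     <dbl> <dbl> <lgl>
#> 1  54.1  -0.116    2.69  0.193    0.123   3.10 TRUE 
#> 2  58.3  -0.863    4.14  0.523    0.127   4.26 TRUE 
#> 3 -20.0   1.59     4.87  0.121    0.0806  2.88 TRUE 
#> 4  40.9   1.53     6.45  0.235    0.0869  3.49 TRUE 
#> # ℹ 196 more rows

# flux accounting (managed cells masked; totals in Tg N yr-1)
fl <- bnf_fluxes(post, cfg$flux$bands)
fl$totals |> filter(flux == "total")
#> # A tibble: 5 × 4
#>   band    total_tg n_cells flux 
#>   <chr>      <dbl>   <int> <chr>
#> 1 60N-90N   0.0701       9 total
#> 2 30N-60N   0.937       38 total
#> 3 30S-30N   5.02        91 total
#> 4 90S-30S   1.02        33 total
#> 5 global    7.05       171 total

# drivers of the inferred fraction
da <- analyse_drivers(post, "f_bnfs",
                      c("temperature", "ecm", "am", "noy", "nhx", "clay"),
                      n_keep = 5, seed = 45)
da$shap$importance
#> # A tibble: 4 × 3
#>   predictor   mean_abs_shap share
#>   <chr>               <dbl> <dbl>
#> 1 ecm                0.0217 0.316
#> 2 temperature        0.0191 0.277
#> 3 noy                0.0156 0.227
#> 4 clay               0.0124 0.180
```

`autoplot(post)`, `autoplot(fl)`, `autoplot(da$shap)` and
`plot_recovery(post)` give the corresponding maps and diagnostics;
`tidy(post)` and `glance(post)` give long-format summaries.

## Running the tests

```r
# after installing the package
testthat::test_dir("tests/testthat", package = "isobnf",
                   load_package = "installed")
```

`tests/testthat/test-acceptance.R` holds one block per acceptance
criterion of the analysis. Two assertions in it fail by design of the
study conditions rather than by bug — the per-cell truth correlation
bound and one prior-spread asymmetry ordering — and are deliberately left
at their stated strength; the methods vignette
(`vignettes/isotope-bnf-methods.Rmd`, identifiability section) explains
why they are unattainable in this noise regime.

## Scope

The package implements the method, not the global data analysis: observed
global BNF totals require external δ¹⁵N compilations, GPP products,
climate and landcover data that are not shipped here. Every number the
test suite asserts is a property of the algorithms on synthetic data with
known truth. See the methods vignette for model assumptions, parameter
defaults and their rationale, numerical choices, and limitations.
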