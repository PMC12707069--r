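clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Synthetic global truth grid
#'
#' Generates a cell table with known true parameters and covariates whose
#' statistical structure emulates the global analysis: a latitudinal
#' temperature gradient (cells placed uniformly on the sphere); strongly
#' anti-correlated ECM and AM fungal abundances (target correlation about
#' -0.9), ECM increasing toward cold climates; a true symbiotic fixation
#' fraction that is a bounded logistic function increasing in temperature
#' and decreasing in ECM abundance, spanning roughly 0.03 (cold) to 0.11
#' (tropical); an uptake fractionation from the mycorrhizal pathway mix; a
#' soil delta15N mean that declines from warm to cold cells (about 6 to 3.5
#' per mil) with Gaussian cell noise; and demand drivers (GPP rising
#' steeply with temperature, fixed allocation and C:N constants,
#' biome-dependent leaf NRE and symbiotic share beta_s).
#'
#' The full generator parameter record is attached as attribute `params`;
#' regenerating from it reproduces the grid bit for bit.
#'
#' @param n_cells Number of grid cells (>= 1).
#' @param seed Integer seed.
#' @param scenario Scenario name; `"global"` is the only built-in.
#' @param config A [default_config()] list (pathway fractionation factors
#'   and soil-isotope noise are read from it).
#' @return A tibble with one row per cell: coordinates and area, climate
#'   and soil covariates, mycorrhizal mix, true `f_bnfs`, `f_depd`,
#'   `eps_u`, `delta_s`, `delta_p` (noise-free forward value), demand
#'   drivers, `demand`, `beta_s`, and logical `natural` mask.
#' @export
make_truth_grid <- function(n_cells = 500, seed = 1, scenario = "global",
                            config = default_config()) {
  stopifnot(n_cells >= 1)
  scenario <- match.arg(scenario)
  pr <- config$priors
  set.seed(seed)

  # uniform on the sphere between 60S and 75N (land-like latitude span)
  lat <- asin(stats::runif(n_cells, sin(-60 * pi / 180),
                           sin(75 * pi / 180))) * 180 / pi
  lon <- stats::runif(n_cells, -180, 180)
  temperature <- 26 - 0.38 * abs(lat) + stats::rnorm(n_cells, 0, 1.5)
  zt <- (temperature - mean(temperature)) / stats::sd(temperature)

  # mycorrhizal abundances: shared latent + temperature give ECM/AM their
  # strong anti-correlation without collapsing onto temperature itself
  eta1 <- stats::rnorm(n_cells)
  ze <- -(0.45 * zt + 0.6 * eta1 + 0.25 * stats::rnorm(n_cells)) / 0.79
  za <- (0.6 * zt + 0.6 * eta1 + 0.18 * stats::rnorm(n_cells)) / 0.868
  ecm <- clamp(0.40 + 0.20 * ze, 0.02, 0.95)
  am <- clamp(0.40 + 0.20 * za, 0.02, 0.95)

  f_ecm <- 0.45 * ecm
  f_am <- 0.5 * am
  f_root <- 1 - f_ecm - f_am
  eps_u <- eps_u_prior_from_mix(f_root, f_am, f_ecm,
                                pr$eps_root, pr$eps_am, pr$eps_ecm)

  f_bnfs <- 0.03 + 0.08 * stats::plogis(
    1.3 * zt - 0.9 * (ecm - mean(ecm)) / stats::sd(ecm) +
      0.3 * stats::rnorm(n_cells))
  delta_s <- 3.5 + 0.10 * pmax(temperature, 0) +
    stats::rnorm(n_cells, 0, config$generator$delta_s_sd)

  # demand drivers: steep tropical-to-boreal GPP contrast, constant
  # allocation and stoichiometry, leaf NRE higher in cold climates
  gpp <- 150 + 2850 * stats::plogis(0.22 * (temperature - 13))
  a_leaf <- 0.25; a_wood <- 0.30; a_root <- 0.20
  cn_leaf <- 25; cn_wood <- 300; cn_root <- 50
  nre_leaf <- clamp(0.40 + 0.006 * (25 - temperature), 0.30, 0.65)
  frec <- f_recycled_tot(gpp, a_leaf, a_wood, a_root,
                         cn_leaf, cn_wood, cn_root,
                         nre_leaf, pr$nre_root, pr$nre_wood)
  f_depd <- clamp(f_depd_prior(pr$f_depd_tot, frec) +
                    stats::rnorm(n_cells, 0, 0.015), 0, 0.5)
  delta_p <- forward_delta_p(f_bnfs, f_depd, eps_u, delta_s,
                             config$constants)

  biome <- dplyr::case_when(
    temperature > 18 ~ "tropical_forest",
    temperature > 6 ~ "temperate_forest",
    TRUE ~ "boreal_forest")
  grass <- stats::runif(n_cells) < 0.25
  biome[grass & temperature > 0] <- "grassland"
  beta_s <- unname(config$flux$beta_s_table[biome])

  grid <- tibble::tibble(
    cell = seq_len(n_cells), lon = lon, lat = lat,
    area = 1.232e10 * cos(lat * pi / 180),
    temperature = temperature, ecm = ecm, am = am,
    n_fixers = clamp(0.10 + 0.25 * stats::plogis(zt) +
                       stats::rnorm(n_cells, 0, 0.05), 0, 1),
    noy = pmax(0.5 + 0.2 * zt + stats::rnorm(n_cells, 0, 0.3), 0.01),
    nhx = pmax(0.6 + 0.1 * zt + stats::rnorm(n_cells, 0, 0.3), 0.01),
    clay = clamp(0.25 + stats::rnorm(n_cells, 0, 0.08), 0.01, 0.8),
    oc = pmax(2 - 0.03 * temperature + stats::rnorm(n_cells, 0, 0.5), 0.1),
    p_pet = pmax(1 + 0.2 * zt + stats::rnorm(n_cells, 0, 0.35), 0.05),
    f_root = f_root, f_am = f_am, f_ecm = f_ecm,
    f_bnfs = f_bnfs, f_depd = f_depd, eps_u = eps_u,
    delta_s = delta_s, delta_p = delta_p,
    gpp = gpp, a_leaf = a_leaf, a_wood = a_wood, a_root = a_root,
    cn_leaf = cn_leaf, cn_wood = cn_wood, cn_root = cn_root,
    nre_leaf = nre_leaf,
    demand = external_n_demand(gpp, a_leaf, a_wood, a_root,
                               cn_leaf, cn_wood, cn_root,
                               nre_leaf, pr$nre_root, pr$nre_wood),
    biome = biome, beta_s = beta_s,
    natural = stats::runif(n_cells) > 0.10
  )
  attr(grid, "params") <- list(n_cells = n_cells, seed = seed,
                               scenario = scenario,
                               generator = config$generator,
                               priors = pr[c("eps_root", "eps_am", "eps_ecm",
                                             "f_depd_tot", "nre_root",
                                             "nre_wood")])
  grid
}

#' Simulate noisy isotope observations from a truth grid
#'
#' Adds independent Gaussian observation noise to the noise-free forward
#' plant signature and to the soil signature. (In the inversion, the
#' flux-weighted propagation of soil-map error into the plant signature is
#' carried by the augmented soil state of the observation operator, so the
#' simulated errors are independent by construction.) Cells whose noisy
#' plant value falls at or below the fixation end-member are flagged
#' invalid.
#'
#' @param truth A [make_truth_grid()] tibble.
#' @param sd_p,sd_s Observation noise SDs (per mil, >= 0).
#' @param seed Integer seed.
#' @param constants An [isotope_constants()] object.
#' @return `truth` with columns `delta_p_obs`, `delta_s_obs`, `sd_p`,
#'   `sd_s` and logical `obs_valid` appended.
#' @export
simulate_observations <- function(truth, sd_p = 0.5, sd_s = 0.5, seed = 1,
                                  constants = isotope_constants()) {
  stopifnot(sd_p >= 0, sd_s >= 0)
  set.seed(seed)
  n <- nrow(truth)
  dp <- truth$delta_p + stats::rnorm(n, 0, sd_p)
  ds <- truth$delta_s + stats::rnorm(n, 0, sd_s)
  dplyr::mutate(truth,
                delta_p_obs = dp, delta_s_obs = ds,
                sd_p = sd_p, sd_s = sd_s,
                obs_valid = check_validity(dp, ds, truth$eps_u,
                                           constants)$valid)
}

#' Synthetic site-level isotope pairs
#'
#' Emulates a small network of natural forests spanning tropical to
#' cool-temperate climates: mean annual temperature spread over about
#' 0--25 degrees C, a true fixation fraction increasing linearly with
#' temperature (0.03 to 0.11 across the range, plus site scatter), soil and
#' plant delta15N from the forward model with observation noise, and one
#' optional planted outlier (anomalously low fixation at high temperature)
#' to exercise the exclusion handling of the site regression.
#'
#' @param n_sites Number of regular sites (>= 3).
#' @param seed Integer seed.
#' @param outlier Add the planted outlier site (flagged by `is_outlier`)?
#' @param sd_obs Observation noise SD for both isotope signatures (per mil).
#' @param config A [default_config()] list.
#' @return A tibble with columns `site`, `mat_c`, `f_bnfs` (truth),
#'   `f_depd`, `eps_u`, `delta_s`, `delta_p`, `sd_p`, `sd_s`, `is_outlier`.
#' @export
make_site_pairs <- function(n_sites = 12, seed = 1, outlier = TRUE,
                            sd_obs = 0.3, config = default_config()) {
  stopifnot(n_sites >= 3)
  pr <- config$priors
  set.seed(seed)
  mat <- seq(1, 25, length.out = n_sites) + stats::rnorm(n_sites, 0, 0.8)
  f_true <- clamp(0.03 + 0.0032 * mat + stats::rnorm(n_sites, 0, 0.006),
                  0.005, 0.5)
  if (outlier) {
    mat <- c(mat, 21)
    f_true <- c(f_true, 0.035)
  }
  n <- length(mat)
  f_ecm <- clamp(0.45 * (0.40 + 0.20 * -(mat - 13) / 8), 0.02, 0.45)
  f_am <- clamp(0.5 * (0.40 + 0.20 * (mat - 13) / 8), 0.02, 0.5)
  eps_u <- eps_u_prior_from_mix(1 - f_ecm - f_am, f_am, f_ecm,
                                pr$eps_root, pr$eps_am, pr$eps_ecm)
  f_depd <- rep(0.12, n)
  delta_s <- 3.5 + 0.10 * mat + stats::rnorm(n, 0, 0.5)
  delta_p <- forward_delta_p(f_true, f_depd, eps_u, delta_s,
                             config$constants) + stats::rnorm(n, 0, sd_obs)
  tibble::tibble(
    site = c(paste0("site_", seq_len(n_sites)),
             if (outlier) "site_outlier"),
    mat_c = mat, f_bnfs = f_true, f_depd = f_depd, eps_u = eps_u,
    delta_s = delta_s + 0 , delta_p = delta_p,
    sd_p = sd_obs, sd_s = sd_obs,
    is_outlier = c(rep(FALSE, n_sites), if (outlier) TRUE)
  )
}
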