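default_units <- c(
  delta_p = "permil", delta_s = "permil", delta_p_true = "permil",
  delta_s_true = "permil", delta_p_obs = "permil", delta_s_obs = "permil",
  delta_s_state = "permil", eps_u = "permil", eps_u_sd = "permil",
  sd_p = "permil", sd_s = "permil",
  gpp = "g C m-2 yr-1", demand = "g N m-2 yr-1",
  bnf_symbiotic = "g N m-2 yr-1", bnf_total = "g N m-2 yr-1",
  total_tg = "Tg N yr-1", baseline_tg = "Tg N yr-1",
  adjusted_tg = "Tg N yr-1", delta_tg = "Tg N yr-1",
  area = "m2", temperature = "degC", mat_c = "degC",
  lat = "degrees_north", lon = "degrees_east"
)

#' Hash a configuration
#'
#' Deterministic MD5 digest of the YAML rendering of a configuration list,
#' used to stamp outputs so runs with different settings are never mixed up.
#'
#' @param config An `isobnf_config` list.
#' @return A hexadecimal digest string.
#' @export
config_hash <- function(config = default_config()) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else unname(x)
  }
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(strip(config)), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a gridded (or site) table with a JSON metadata sidecar
#'
#' Writes the table as plain CSV with full double precision (`%.17g`, so a
#' read-back is bit-identical) and a `<path>.json` sidecar recording column
#' classes, units for recognised quantities, row count and any extra
#' metadata (typically the configuration hash and seed). The sidecar
#' contains no timestamps, so repeated writes of the same table are
#' byte-identical.
#'
#' @param table A data frame.
#' @param path Output CSV path.
#' @param meta Named list of extra metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(table, path, meta = list()) {
  stopifnot(is.data.frame(table))
  out <- as.data.frame(lapply(table, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  }), optional = TRUE, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  sidecar <- c(list(
    columns = lapply(table, function(col) class(col)[1]),
    units = as.list(default_units[intersect(names(default_units),
                                            names(table))]),
    n_rows = nrow(table)
  ), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a table written by [write_grid_csv()]
#'
#' Restores column classes from the JSON sidecar and validates that the
#' stored schema matches, naming any missing or extra column.
#'
#' @param path CSV path (its `.json` sidecar must sit next to it).
#' @return A list: `table` (tibble) and `meta` (the sidecar list).
#' @export
read_grid_csv <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(sidecar_path)) {
    stop("missing metadata sidecar: ", sidecar_path)
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE)
  missing_cols <- setdiff(names(meta$columns), names(raw))
  extra_cols <- setdiff(names(raw), names(meta$columns))
  if (length(missing_cols) || length(extra_cols)) {
    stop("schema mismatch for ", path,
         if (length(missing_cols))
           paste0("; missing: ", paste(missing_cols, collapse = ", ")),
         if (length(extra_cols))
           paste0("; unexpected: ", paste(extra_cols, collapse = ", ")))
  }
  table <- tibble::as_tibble(purrr::imap(raw, function(col, nm) {
    switch(meta$columns[[nm]],
           numeric = as.numeric(col),
           integer = as.integer(col),
           logical = as.logical(col),
           col)
  }))
  list(table = table, meta = meta)
}

#' Prepare a simulated grid for inversion
#'
#' Renames the generator truth columns of a [simulate_observations()] result
#' to `*_true` and promotes the noisy observations to the `delta_p` /
#' `delta_s` columns that [build_priors()] and [invert_grid()] read, so the
#' simulated grid has the same schema as a real observed grid while keeping
#' the truth available for validation.
#'
#' @param grid A tibble from [simulate_observations()].
#' @return The same tibble with truth columns suffixed `_true` and
#'   observation columns renamed to `delta_p` and `delta_s`.
#' @export
#' @examples
#' truth <- make_truth_grid(n_cells = 5, seed = 1)
#' obs <- simulate_observations(truth, seed = 2)
#' names(rename_truth(obs))
rename_truth <- function(grid) {
  dplyr::rename(grid,
                f_bnfs_true = "f_bnfs", f_depd_true = "f_depd",
                eps_u_true = "eps_u", delta_p_true = "delta_p",
                delta_s_true = "delta_s") |>
    dplyr::rename(delta_p = "delta_p_obs", delta_s = "delta_s_obs")
}

stage_input <- function(out_dir, file, stage, producer) {
  path <- file.path(out_dir, file)
  if (!file.exists(path)) {
    stop("stage '", stage, "' needs ", file,
         ", which is produced by stage '", producer,
         "'; run that stage first (or include it in `stages`)")
  }
  read_grid_csv(path)$table
}

#' Run the full inference pipeline
#'
#' Executes the requested stages in their canonical order, writing every
#' product as CSV + JSON sidecar under `out_dir` together with a
#' `manifest.json` recording the seed, the configuration hash and per-stage
#' wall-clock seconds. Stages:
#' \describe{
#'   \item{simulate}{Synthetic truth grid with noisy observations
#'     (`grid.csv`) and synthetic site pairs (`sites.csv`).}
#'   \item{invert-sites}{Site-level ensemble inversion
#'     (`sites_posterior.csv`) and the temperature regression of the
#'     posterior fixation fraction with the planted outlier excluded
#'     (`site_regression.csv`).}
#'   \item{invert-grid}{Per-cell priors and ensemble inversion of the grid
#'     (`grid_posterior.csv`).}
#'   \item{fluxes}{Flux accounting of the posterior grid
#'     (`flux_totals.csv`) and the transient plant-delta15N adjustment
#'     (`transient_totals.csv`).}
#'   \item{drivers}{Feature selection, forest upscaler and Shapley report
#'     on the posterior fixation fraction (`driver_importance.csv`).}
#' }
#' Later stages read their inputs from `out_dir`, so a stage whose
#' dependency has not been produced fails with the missing stage named.
#' All randomness derives from `seed`.
#'
#' @param out_dir Output directory (created if absent).
#' @param stages Character subset of the stage names above.
#' @param seed Integer root seed.
#' @param config A [default_config()] list.
#' @param n_cells,n_sites Synthetic problem sizes for the simulate stage.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(out_dir,
                         stages = c("simulate", "invert-sites",
                                    "invert-grid", "fluxes", "drivers"),
                         seed = 1, config = default_config(),
                         n_cells = 500, n_sites = 12) {
  all_stages <- c("simulate", "invert-sites", "invert-grid", "fluxes",
                  "drivers")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  }
  stages <- all_stages[all_stages %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  meta <- list(config_hash = hash, seed = seed)
  manifest <- list(seed = seed, config_hash = hash, stages = list())
  timed <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    outputs <- fun()
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = outputs)
  }

  if ("simulate" %in% stages) {
    timed("simulate", function() {
      truth <- make_truth_grid(n_cells, derive_seed(seed, 1L),
                               config = config)
      obs <- simulate_observations(truth, config$generator$sd_p,
                                   config$generator$sd_s,
                                   derive_seed(seed, 2L), config$constants)
      write_grid_csv(rename_truth(obs), file.path(out_dir, "grid.csv"), meta)
      sites <- make_site_pairs(n_sites, derive_seed(seed, 3L),
                               config = config) |>
        dplyr::rename(f_bnfs_true = "f_bnfs", f_depd_true = "f_depd",
                      eps_u_true = "eps_u") |>
        # the synthetic sites carry a mix-derived fractionation prior; real
        # site tables without one fall back to the configuration constants
        dplyr::mutate(prior_eps_u_mean = .data$eps_u_true,
                      prior_eps_u_sd = config$priors$eps_u_sd)
      write_grid_csv(sites, file.path(out_dir, "sites.csv"), meta)
      c("grid.csv", "sites.csv")
    })
  }

  if ("invert-sites" %in% stages) {
    timed("invert-sites", function() {
      sites <- stage_input(out_dir, "sites.csv", "invert-sites", "simulate")
      inv_cfg <- config$inversion
      inv_cfg$seed <- derive_seed(seed, 4L)
      post <- invert_sites(sites, config, inv_cfg)
      write_grid_csv(post, file.path(out_dir, "sites_posterior.csv"), meta)
      reg <- site_temperature_regression(
        post, exclude = post$site[post$is_outlier], config$constants)
      write_grid_csv(reg, file.path(out_dir, "site_regression.csv"), meta)
      c("sites_posterior.csv", "site_regression.csv")
    })
  }

  if ("invert-grid" %in% stages) {
    timed("invert-grid", function() {
      grid <- stage_input(out_dir, "grid.csv", "invert-grid", "simulate")
      grid <- build_priors(grid, config, derive_seed(seed, 5L))
      inv_cfg <- config$inversion
      inv_cfg$seed <- derive_seed(seed, 6L)
      post <- invert_grid(grid, config$constants, inv_cfg)
      write_grid_csv(post, file.path(out_dir, "grid_posterior.csv"), meta)
      "grid_posterior.csv"
    })
  }

  if ("fluxes" %in% stages) {
    timed("fluxes", function() {
      post <- stage_input(out_dir, "grid_posterior.csv", "fluxes",
                          "invert-grid")
      fl <- bnf_fluxes(post, config$flux$bands)
      write_grid_csv(fl$totals, file.path(out_dir, "flux_totals.csv"),
                     c(meta, list(n_capped = fl$n_capped)))
      tr <- transient_adjustment(post, shift = -1.6, config$constants,
                                 config$flux$bands)
      write_grid_csv(tr$totals, file.path(out_dir, "transient_totals.csv"),
                     c(meta, list(shift = tr$shift,
                                  n_invalid = tr$n_invalid)))
      c("flux_totals.csv", "transient_totals.csv")
    })
  }

  if ("drivers" %in% stages) {
    timed("drivers", function() {
      post <- stage_input(out_dir, "grid_posterior.csv", "drivers",
                          "invert-grid")
      predictors <- c("temperature", "ecm", "am", "n_fixers", "noy", "nhx",
                      "clay", "oc", "p_pet")
      da <- analyse_drivers(post, "f_bnfs", predictors, n_keep = 6,
                            seed = derive_seed(seed, 7L))
      write_grid_csv(da$shap$importance,
                     file.path(out_dir, "driver_importance.csv"),
                     c(meta, list(r2_cv = da$model$r2_cv,
                                  retained = da$vif$retained)))
      "driver_importance.csv"
    })
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
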