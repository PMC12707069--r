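#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an inverted grid
#'
#' One row per cell and parameter, broom-style: `term` is one of `f_bnfs`,
#' `f_depd`, `eps_u`, with the posterior mean as `estimate` and the
#' posterior ensemble SD as `std.error`.
#'
#' @param x A `bnf_inversion` object from [invert_grid()].
#' @param ... Unused.
#' @return A tibble with columns `cell` (row number if absent from the
#'   grid), `term`, `estimate`, `std.error`, `valid`.
#' @method tidy bnf_inversion
#' @export
tidy.bnf_inversion <- function(x, ...) {
  cell <- if ("cell" %in% names(x)) x$cell else seq_len(nrow(x))
  purrr::map_dfr(c("f_bnfs", "f_depd", "eps_u"), function(nm) {
    tibble::tibble(cell = cell, term = nm,
                   estimate = x[[nm]],
                   std.error = x[[paste0(nm, "_sd")]],
                   valid = x$valid)
  }) |>
    dplyr::arrange(.data$cell)
}

#' Summarise an inverted grid in one row
#'
#' @param x A `bnf_inversion` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_cells`, `n_valid`, `n_converged`,
#'   `mean_f_bnfs` (over valid cells), `mean_f_bnfs_sd`,
#'   `mean_repeat_spread`.
#' @method glance bnf_inversion
#' @export
glance.bnf_inversion <- function(x, ...) {
  v <- x$valid
  tibble::tibble(
    n_cells = nrow(x),
    n_valid = sum(v),
    n_converged = sum(x$converged[v]),
    mean_f_bnfs = mean(x$f_bnfs[v]),
    mean_f_bnfs_sd = mean(x$f_bnfs_sd[v]),
    mean_repeat_spread = mean(x$repeat_spread_f_bnfs[v])
  )
}

#' Tidy an upscaler's cross-validation
#'
#' @param x A `bnf_upscaler` object from [fit_upscaler()].
#' @param ... Unused.
#' @return The per-fold tibble (`fold`, `r2`).
#' @method tidy bnf_upscaler
#' @export
tidy.bnf_upscaler <- function(x, ...) x$cv

#' Summarise an upscaler in one row
#'
#' @param x A `bnf_upscaler` object.
#' @param ... Unused.
#' @return A one-row tibble: `r2_cv`, `k_folds`, `n_obs`, `n_predictors`,
#'   `n_trees`.
#' @method glance bnf_upscaler
#' @export
glance.bnf_upscaler <- function(x, ...) {
  tibble::tibble(r2_cv = x$r2_cv, k_folds = nrow(x$cv),
                 n_obs = nrow(x$data),
                 n_predictors = length(x$predictors),
                 n_trees = x$model$num.trees)
}

#' Tidy a Shapley report
#'
#' @param x A `shap_report` object.
#' @param ... Unused.
#' @return The importance table with broom-style names: `term`,
#'   `estimate` (mean absolute Shapley value), `share`.
#' @method tidy shap_report
#' @export
tidy.shap_report <- function(x, ...) {
  dplyr::rename(x$importance, term = "predictor",
                estimate = "mean_abs_shap")
}

#' Summarise a Shapley report in one row
#'
#' @param x A `shap_report` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_predictors`, `n_rows`, `top_predictor`,
#'   `top_share`.
#' @method glance shap_report
#' @export
glance.shap_report <- function(x, ...) {
  tibble::tibble(n_predictors = nrow(x$importance),
                 n_rows = length(unique(x$shap$row)),
                 top_predictor = x$importance$predictor[1],
                 top_share = x$importance$share[1])
}

#' Tidy a driver analysis
#'
#' @param x A `driver_analysis` object from [analyse_drivers()].
#' @param ... Unused.
#' @return The Shapley importance table (see [tidy.shap_report()]).
#' @method tidy driver_analysis
#' @export
tidy.driver_analysis <- function(x, ...) tidy(x$shap)

#' Summarise a driver analysis in one row
#'
#' @param x A `driver_analysis` object.
#' @param ... Unused.
#' @return A one-row tibble: `r2_cv`, `n_selected` (after elimination),
#'   `n_retained` (after the VIF filter), `top_predictor`.
#' @method glance driver_analysis
#' @export
glance.driver_analysis <- function(x, ...) {
  tibble::tibble(r2_cv = x$model$r2_cv,
                 n_selected = length(x$rfe),
                 n_retained = length(x$vif$retained),
                 top_predictor = x$shap$importance$predictor[1])
}

#' Tidy flux totals
#'
#' @param x A `bnf_fluxes` object from [bnf_fluxes()].
#' @param ... Unused.
#' @return The band/global totals tibble (`band`, `total_tg`, `n_cells`,
#'   `flux`).
#' @method tidy bnf_fluxes
#' @export
tidy.bnf_fluxes <- function(x, ...) x$totals

#' Summarise flux totals in one row
#'
#' @param x A `bnf_fluxes` object.
#' @param ... Unused.
#' @return A one-row tibble: `global_symbiotic_tg`, `global_total_tg`,
#'   `n_cells`, `n_capped`.
#' @method glance bnf_fluxes
#' @export
glance.bnf_fluxes <- function(x, ...) {
  g <- dplyr::filter(x$totals, .data$band == "global")
  tibble::tibble(
    global_symbiotic_tg = g$total_tg[g$flux == "symbiotic"],
    global_total_tg = g$total_tg[g$flux == "total"],
    n_cells = nrow(x$grid),
    n_capped = x$n_capped
  )
}
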