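#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Map the posterior fixation fraction
#'
#' Point map of the posterior symbiotic fixation fraction over cell
#' coordinates; invalid cells are drawn hollow.
#'
#' @param object A `bnf_inversion` object from [invert_grid()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bnf_inversion
#' @export
autoplot.bnf_inversion <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lon, .data$lat)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$f_bnfs,
                                     shape = .data$valid), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "valid") +
    ggplot2::scale_colour_viridis_c(name = expression(f[BNFs])) +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  title = "Posterior symbiotic fixation fraction") +
    ggplot2::theme_minimal()
}

#' Plot band and global BNF totals
#'
#' Grouped bars of the symbiotic and total fixation flux per latitudinal
#' band and globally.
#'
#' @param object A `bnf_fluxes` object from [bnf_fluxes()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bnf_fluxes
#' @export
autoplot.bnf_fluxes <- function(object, ...) {
  totals <- dplyr::mutate(object$totals,
                          band = factor(.data$band,
                                        levels = unique(.data$band)))
  ggplot2::ggplot(totals, ggplot2::aes(.data$band, .data$total_tg,
                                       fill = .data$flux)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "BNF (Tg N yr-1)", fill = NULL,
                  title = "Fixation flux by latitudinal band") +
    ggplot2::theme_minimal()
}

#' Plot Shapley importance shares
#'
#' Horizontal bars of the mean absolute Shapley value per predictor.
#'
#' @param object A `shap_report` object from [shap_report()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot shap_report
#' @export
autoplot.shap_report <- function(object, ...) {
  imp <- dplyr::mutate(object$importance,
                       predictor = stats::reorder(.data$predictor,
                                                  .data$mean_abs_shap))
  ggplot2::ggplot(imp, ggplot2::aes(.data$mean_abs_shap, .data$predictor)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Mean |Shapley value|", y = NULL,
                  title = "Driver importance") +
    ggplot2::theme_minimal()
}

#' Shapley partial-dependence curves
#'
#' Binned mean Shapley value against predictor value, one facet per
#' predictor (free x scales).
#'
#' @param report A `shap_report` object.
#' @param predictors Predictors to show (default all).
#' @return A ggplot.
#' @export
plot_partial_dependence <- function(report, predictors = NULL) {
  stopifnot(inherits(report, "shap_report"))
  pd <- report$partial_dependence
  if (!is.null(predictors)) {
    pd <- dplyr::filter(pd, .data$predictor %in% predictors)
  }
  ggplot2::ggplot(pd, ggplot2::aes(.data$x, .data$shap)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$predictor), scales = "free_x") +
    ggplot2::labs(x = "Predictor value", y = "Mean Shapley value",
                  title = "Partial dependence of the fixation fraction") +
    ggplot2::theme_minimal()
}

#' Posterior versus truth scatter
#'
#' Diagnostic scatter of posterior against true fixation fractions for a
#' synthetic experiment, with the 1:1 line.
#'
#' @param inversion A `bnf_inversion` object whose grid retains a
#'   `f_bnfs_true` column.
#' @return A ggplot.
#' @export
plot_recovery <- function(inversion) {
  stopifnot("f_bnfs_true" %in% names(inversion))
  ggplot2::ggplot(dplyr::filter(inversion, .data$valid),
                  ggplot2::aes(.data$f_bnfs_true, .data$f_bnfs)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$f_bnfs - .data$f_bnfs_sd,
      ymax = .data$f_bnfs + .data$f_bnfs_sd), alpha = 0.5) +
    ggplot2::labs(x = "True fixation fraction",
                  y = "Posterior fixation fraction",
                  title = "Synthetic recovery") +
    ggplot2::theme_minimal()
}
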