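#' Shapley attribution of forest predictions
#'
#' Monte-Carlo permutation estimate of interventional Shapley values
#' (Strumbelj & Kononenko sampling): for each evaluation row and each of
#' `n_perm` random feature orderings, features are switched one by one from
#' a background row's values to the evaluation row's values, and the
#' successive prediction differences are the marginal contributions. The
#' estimator is unbiased for the interventional Shapley value and additive
#' up to Monte-Carlo noise: contributions per row sum to the prediction
#' minus the background mean prediction.
#'
#' Importance is summarised as the mean absolute Shapley value per
#' predictor, normalised to shares summing to 1; partial dependence as
#' binned means of the (predictor value, Shapley value) scatter over 20
#' quantile bins.
#'
#' @param model A [fit_upscaler()] object (or a bare `ranger` model plus
#'   `predictors`).
#' @param data Evaluation rows (defaults to the upscaler's training data).
#' @param predictors Predictor names (defaults to the upscaler's).
#' @param n_perm Random feature orderings per evaluation row (default 20).
#' @param n_eval Maximum number of evaluation rows (sampled without
#'   replacement when `data` is larger; default 300).
#' @param n_bins Quantile bins of the partial-dependence summary.
#' @param seed Integer seed; the report is deterministic given it.
#' @return A list of class `shap_report`: `shap` (long tibble of per-row
#'   values), `importance` (tibble with `predictor`, `mean_abs_shap`,
#'   `share`, sorted descending), `partial_dependence` (tibble with
#'   `predictor`, `bin`, `x`, `shap`).
#' @export
shap_report <- function(model, data = NULL, predictors = NULL,
                        n_perm = 20, n_eval = 300, n_bins = 20, seed = 1) {
  if (inherits(model, "bnf_upscaler")) {
    predictors <- predictors %||% model$predictors
    data <- data %||% model$data
    model <- model$model
  }
  stopifnot(!is.null(predictors), !is.null(data),
            all(predictors %in% names(data)), n_perm >= 1)
  x <- as.data.frame(dplyr::select(data, dplyr::all_of(predictors)))
  set.seed(seed)
  eval_idx <- if (nrow(x) > n_eval) sort(sample.int(nrow(x), n_eval)) else
    seq_len(nrow(x))
  xe <- x[eval_idx, , drop = FALSE]
  n <- nrow(xe)
  p <- length(predictors)
  phi <- matrix(0, n, p, dimnames = list(NULL, predictors))
  for (m in seq_len(n_perm)) {
    ord <- sample.int(p)
    bg <- x[sample.int(nrow(x), n, replace = TRUE), , drop = FALSE]
    # build the p + 1 hybrid rows per evaluation point in one batch
    hybrids <- vector("list", p + 1L)
    cur <- bg
    hybrids[[1L]] <- cur
    for (j in seq_len(p)) {
      cur[[predictors[ord[j]]]] <- xe[[predictors[ord[j]]]]
      hybrids[[j + 1L]] <- cur
    }
    preds <- stats::predict(model, dplyr::bind_rows(hybrids))$predictions
    preds <- matrix(preds, nrow = n)         # n x (p + 1)
    contrib <- preds[, -1L, drop = FALSE] - preds[, -(p + 1L), drop = FALSE]
    phi[, ord] <- phi[, ord] + contrib / n_perm
  }
  shap_long <- tibble::tibble(
    row = rep(eval_idx, p),
    predictor = rep(predictors, each = n),
    x = as.vector(as.matrix(xe)),
    shap = as.vector(phi)
  )
  importance <- shap_long |>
    dplyr::group_by(.data$predictor) |>
    dplyr::summarise(mean_abs_shap = mean(abs(.data$shap)),
                     .groups = "drop") |>
    dplyr::mutate(share = .data$mean_abs_shap / sum(.data$mean_abs_shap)) |>
    dplyr::arrange(dplyr::desc(.data$share))
  pd <- shap_long |>
    dplyr::group_by(.data$predictor) |>
    dplyr::mutate(bin = dplyr::ntile(.data$x, n_bins)) |>
    dplyr::group_by(.data$predictor, .data$bin) |>
    dplyr::summarise(x = mean(.data$x), shap = mean(.data$shap),
                     .groups = "drop")
  structure(list(shap = shap_long, importance = importance,
                 partial_dependence = pd),
            class = "shap_report")
}

#' @export
print.shap_report <- function(x, ...) {
  cat("Shapley importance shares:\n")
  print(x$importance)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full driver-analysis pipeline
#'
#' Chains the feature-selection procedure used for the fixation-fraction
#' driver analysis: recursive feature elimination to `n_keep` predictors,
#' multicollinearity filtering to VIF < `vif_threshold`, a cross-validated
#' regression forest on the retained set, and a Shapley
#' importance/partial-dependence report.
#'
#' @inheritParams fit_upscaler
#' @param n_keep Predictors retained by the elimination stage.
#' @param vif_threshold VIF threshold of the collinearity stage.
#' @param n_perm,n_eval Shapley sampling effort (see [shap_report()]).
#' @return A list of class `driver_analysis`: `rfe` (names), `vif`
#'   (the [vif_filter()] result), `model` ([fit_upscaler()] object),
#'   `shap` ([shap_report()] object).
#' @export
analyse_drivers <- function(data, response, predictors, n_keep = 10,
                            vif_threshold = 5, k_folds = 10, n_trees = 500,
                            n_perm = 20, n_eval = 300, seed = 1) {
  kept <- rfe_select(data, response, predictors,
                     n_keep = min(n_keep, length(predictors)),
                     n_trees = n_trees, seed = seed)
  vf <- vif_filter(data, kept, threshold = vif_threshold)
  model <- fit_upscaler(data, response, vf$retained, k_folds = k_folds,
                        n_trees = n_trees, seed = seed)
  shap <- shap_report(model, n_perm = n_perm, n_eval = n_eval, seed = seed)
  structure(list(rfe = kept, vif = vf, model = model, shap = shap),
            class = "driver_analysis")
}

#' @export
print.driver_analysis <- function(x, ...) {
  cat("Driver analysis:", length(x$rfe), "predictors after elimination,",
      length(x$vif$retained), "after VIF filtering\n")
  print(x$model)
  print(x$shap)
  invisible(x)
}
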