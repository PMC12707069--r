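#' Aggregate point observations onto a regular grid
#'
#' Arithmetic mean of point values per `cell_size`-degree cell (cell indices
#' from the floored scaled coordinates; cell centres reported). Empty cells
#' are absent from the output.
#'
#' @param points Tibble with columns `lon`, `lat`, `value`.
#' @param cell_size Cell edge in degrees (> 0).
#' @return A tibble with `lon`, `lat` (cell centres), `value` (cell mean)
#'   and `n` (point count).
#' @export
aggregate_points <- function(points, cell_size = 0.1) {
  stopifnot(cell_size > 0, all(points$lon >= -180), all(points$lon <= 180),
            all(points$lat >= -90), all(points$lat <= 90))
  points |>
    dplyr::mutate(ix = floor(.data$lon / cell_size),
                  iy = floor(.data$lat / cell_size)) |>
    dplyr::group_by(.data$ix, .data$iy) |>
    dplyr::summarise(value = mean(.data$value), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::transmute(lon = (.data$ix + 0.5) * cell_size,
                     lat = (.data$iy + 0.5) * cell_size,
                     value = .data$value, n = .data$n)
}

#' Fit a regression-forest upscaler with K-fold cross-validation
#'
#' Random-forest regression of a gridded response on gridded predictors,
#' with a seeded K-fold cross-validation report (per-fold and mean R
#' squared). The returned model is trained on all rows.
#'
#' @param data Tibble holding response and predictors.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor column names.
#' @param k_folds Number of cross-validation folds (default 10).
#' @param n_trees Trees per forest (default 500).
#' @param seed Integer seed; the fold assignment and forests are
#'   deterministic given it.
#' @return An object of class `bnf_upscaler`: `model` (ranger), `cv`
#'   (per-fold tibble), `r2_cv` (mean out-of-fold R squared), `response`,
#'   `predictors`.
#' @export
fit_upscaler <- function(data, response, predictors, k_folds = 10,
                         n_trees = 500, seed = 1) {
  stopifnot(response %in% names(data), all(predictors %in% names(data)),
            k_folds >= 2)
  data <- dplyr::select(data, dplyr::all_of(c(response, predictors))) |>
    stats::na.omit()
  if (nrow(data) < k_folds) {
    stop("need at least k_folds = ", k_folds, " rows with complete data")
  }
  form <- stats::reformulate(predictors, response)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k_folds), nrow(data)))
  cv <- purrr::map_dfr(seq_len(k_folds), function(k) {
    fit <- ranger::ranger(form, data = data[fold != k, ],
                          num.trees = n_trees, seed = seed + k)
    pred <- stats::predict(fit, data[fold == k, ])$predictions
    truth <- data[[response]][fold == k]
    tibble::tibble(fold = k,
                   r2 = 1 - sum((truth - pred)^2) /
                     sum((truth - mean(truth))^2))
  })
  model <- ranger::ranger(form, data = data, num.trees = n_trees,
                          seed = seed, importance = "impurity")
  structure(list(model = model, cv = cv, r2_cv = mean(cv$r2),
                 response = response, predictors = predictors,
                 data = data),
            class = "bnf_upscaler")
}

#' @export
print.bnf_upscaler <- function(x, ...) {
  cat("Regression-forest upscaler:", x$response, "~",
      paste(x$predictors, collapse = " + "), "\n")
  cat(sprintf("%d-fold CV R2 = %.3f\n", nrow(x$cv), x$r2_cv))
  invisible(x)
}

vif_table <- function(data, predictors) {
  purrr::map_dbl(predictors, function(p) {
    # exact collinearity gives a perfect fit by construction; the ensuing
    # summary.lm warning is expected here, not a defect
    r2 <- suppressWarnings(
      summary(stats::lm(stats::reformulate(setdiff(predictors, p), p),
                        data = data))$r.squared)
    1 / max(1 - r2, 1e-12)
  }) |>
    (\(v) tibble::tibble(predictor = predictors, vif = v))()
}

#' Multicollinearity filtering by variance inflation factor
#'
#' Computes the VIF (\eqn{1/(1-R^2)} of each predictor regressed on the
#' others). While any VIF exceeds the threshold, the most correlated pair
#' involving an offending predictor is identified and one member is dropped:
#' the one with the larger mean absolute correlation to all remaining
#' predictors (ties broken by name order). Constant predictors are dropped
#' up front with a warning.
#'
#' @param data Tibble holding the predictors.
#' @param predictors Character vector of predictor names (>= 2).
#' @param threshold VIF threshold (default 5).
#' @return A list: `retained` (names), `vif` (final VIF table), `dropped`
#'   (tibble with `predictor`, `reason`, `abs_cor` of the pair that
#'   triggered the drop).
#' @export
vif_filter <- function(data, predictors, threshold = 5) {
  stopifnot(length(predictors) >= 2, all(predictors %in% names(data)))
  data <- stats::na.omit(dplyr::select(data, dplyr::all_of(predictors)))
  constant <- predictors[purrr::map_lgl(predictors,
                                        ~ stats::sd(data[[.x]]) == 0)]
  if (length(constant)) {
    warning("dropping constant predictor(s): ",
            paste(constant, collapse = ", "))
  }
  retained <- setdiff(predictors, constant)
  dropped <- tibble::tibble(predictor = constant,
                            reason = rep("constant", length(constant)),
                            abs_cor = NA_real_)
  repeat {
    if (length(retained) < 2) break
    vt <- vif_table(data, retained)
    if (all(vt$vif <= threshold)) break
    offenders <- vt$predictor[vt$vif > threshold]
    cm <- abs(stats::cor(data[retained]))
    diag(cm) <- 0
    # most correlated pair involving an offender
    sub <- cm[offenders, , drop = FALSE]
    idx <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pair <- sort(c(offenders[idx[1]], colnames(sub)[idx[2]]))
    mean_cor <- purrr::map_dbl(pair, function(p)
      mean(cm[p, setdiff(retained, pair)]))
    drop <- if (isTRUE(all.equal(mean_cor[1], mean_cor[2]))) pair[1] else
      pair[which.max(mean_cor)]
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      predictor = drop, reason = paste("collinear with", setdiff(pair, drop)),
      abs_cor = cm[pair[1], pair[2]]))
    retained <- setdiff(retained, drop)
  }
  list(retained = retained,
       vif = if (length(retained) >= 2) vif_table(data, retained) else
         tibble::tibble(predictor = retained, vif = 1),
       dropped = dropped)
}

#' Recursive feature elimination by forest importance
#'
#' Iteratively refits the forest and drops the predictor with the smallest
#' impurity importance until `n_keep` remain.
#'
#' @inheritParams fit_upscaler
#' @param n_keep Number of predictors to retain.
#' @return Character vector of retained predictor names (a subset of
#'   `predictors`, original order preserved).
#' @export
rfe_select <- function(data, response, predictors, n_keep,
                       n_trees = 500, seed = 1) {
  stopifnot(n_keep >= 1, n_keep <= length(predictors))
  current <- predictors
  while (length(current) > n_keep) {
    fit <- ranger::ranger(stats::reformulate(current, response),
                          data = data, num.trees = n_trees,
                          importance = "impurity", seed = seed)
    imp <- ranger::importance(fit)
    current <- setdiff(current, names(which.min(imp)))
  }
  predictors[predictors %in% current]
}

#' Site-level regression of the fixation fraction on temperature
#'
#' Ordinary least squares of site `f_bnfs` on mean annual temperature,
#' after excluding listed outlier sites and any site whose plant delta15N
#' lies at or below the fixation end-member (where the mass balance is not
#' invertible).
#'
#' @param sites Tibble with columns `f_bnfs`, `mat_c` and optionally `site`
#'   and `delta_p`.
#' @param exclude Character vector of site identifiers to exclude.
#' @param constants An [isotope_constants()] object (for the validity rule).
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `p_value`
#'   (OLS t-test on the slope), `n_used`, `n_excluded`.
#' @export
site_temperature_regression <- function(sites, exclude = character(),
                                        constants = isotope_constants()) {
  used <- sites
  if ("site" %in% names(used) && length(exclude)) {
    used <- dplyr::filter(used, !.data$site %in% exclude)
  }
  if ("delta_p" %in% names(used)) {
    used <- dplyr::filter(used, .data$delta_p > constants$delta_bnf)
  }
  if (nrow(used) < 3) stop("need at least 3 sites after exclusions")
  if (stats::sd(used$mat_c) == 0) {
    stop("degenerate regression: mean annual temperature has no variance")
  }
  fit <- stats::lm(f_bnfs ~ mat_c, data = used)
  sm <- summary(fit)
  out <- tibble::tibble(
    slope = stats::coef(fit)[["mat_c"]],
    intercept = stats::coef(fit)[["(Intercept)"]],
    r_squared = sm$r.squared,
    p_value = sm$coefficients["mat_c", "Pr(>|t|)"],
    n_used = nrow(used),
    n_excluded = nrow(sites) - nrow(used)
  )
  attr(out, "fit") <- fit
  out
}
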