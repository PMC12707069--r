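test_that("point aggregation conserves counts and averages cells", {
  pts <- tibble::tibble(
    lon = c(10.01, 10.02, 10.31, -5.99),
    lat = c(50.01, 50.02, 50.01, -3.55),
    value = c(1, 3, 10, 7))
  out <- aggregate_points(pts, cell_size = 0.1)
  expect_equal(sum(out$n), nrow(pts))
  # the two co-located points average to 2 at the cell centre
  cell <- out[abs(out$lon - 10.05) < 1e-9 & abs(out$lat - 50.05) < 1e-9, ]
  expect_equal(cell$value, 2)
  expect_equal(cell$n, 2L)
  expect_equal(nrow(out), 3)
  expect_error(aggregate_points(dplyr::mutate(pts, lon = 400)))
})

test_that("vif_filter removes a near-duplicate and terminates below the
           threshold", {
  set.seed(31)
  n <- 300
  x <- rnorm(n)
  d <- tibble::tibble(a = x, b = x + rnorm(n, 0, 0.01), c = rnorm(n))
  out <- vif_filter(d, c("a", "b", "c"), threshold = 5)
  expect_equal(length(out$retained), 2)
  expect_true("c" %in% out$retained)
  expect_true(all(out$vif$vif < 5))
  expect_equal(nrow(out$dropped), 1)
})

test_that("vif_filter handles an exact linear combination x + y", {
  set.seed(32)
  n <- 300
  d <- tibble::tibble(x = rnorm(n), y = rnorm(n))
  d$z <- d$x + d$y
  out <- vif_filter(d, c("x", "y", "z"), threshold = 5)
  expect_true(all(out$vif$vif < 5))
  expect_lt(length(out$retained), 3)
})

test_that("vif_filter is a no-op when all VIF are already below threshold", {
  set.seed(33)
  d <- tibble::tibble(x = rnorm(100), y = rnorm(100), z = rnorm(100))
  out <- vif_filter(d, c("x", "y", "z"))
  expect_equal(out$retained, c("x", "y", "z"))
  expect_equal(nrow(dplyr::filter(out$dropped, reason != "constant")), 0)
})

test_that("vif_filter warns on constant predictors", {
  d <- tibble::tibble(x = rnorm(50), k = 1)
  expect_warning(out <- vif_filter(d, c("x", "k")), "constant")
  expect_equal(out$retained, "x")
})

test_that("recursive elimination keeps planted signal predictors", {
  set.seed(34)
  n <- 400
  d <- tibble::tibble(s1 = rnorm(n), s2 = rnorm(n),
                      n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  d$y <- 2 * d$s1 - 1.5 * d$s2 + rnorm(n, 0, 0.1)
  kept <- rfe_select(d, "y", c("s1", "s2", "n1", "n2", "n3"), n_keep = 2,
                     seed = 1)
  expect_setequal(kept, c("s1", "s2"))
  # identity when nothing is eliminated
  expect_equal(rfe_select(d, "y", c("s1", "s2"), n_keep = 2), c("s1", "s2"))
})

test_that("upscaler learns a learnable response and not a null one", {
  set.seed(35)
  n <- 500
  d <- tibble::tibble(x1 = runif(n), x2 = runif(n))
  d$y_learn <- sin(2 * pi * d$x1) + d$x2
  d$y_null <- rnorm(n)
  up <- fit_upscaler(d, "y_learn", c("x1", "x2"), k_folds = 5, seed = 2)
  expect_gt(up$r2_cv, 0.9)
  null <- fit_upscaler(d, "y_null", c("x1", "x2"), k_folds = 5, seed = 2)
  expect_lt(null$r2_cv, 0.1)
  # seeded determinism
  up2 <- fit_upscaler(d, "y_learn", c("x1", "x2"), k_folds = 5, seed = 2)
  expect_identical(up$cv, up2$cv)
  expect_identical(up$r2_cv, up2$r2_cv)
  # tidiers
  expect_equal(nrow(tidy(up)), 5)
  expect_equal(glance(up)$n_predictors, 2)
})

test_that("Shapley report is additive, finds the planted driver and is
           deterministic", {
  set.seed(36)
  n <- 400
  d <- tibble::tibble(big = runif(n), small = runif(n), none = runif(n))
  d$y <- 3 * d$big + 0.3 * d$small + rnorm(n, 0, 0.05)
  up <- fit_upscaler(d, "y", c("big", "small", "none"), k_folds = 5,
                     seed = 3)
  sh <- shap_report(up, n_perm = 10, n_eval = 150, seed = 4)
  expect_equal(sum(sh$importance$share), 1, tolerance = 1e-9)
  expect_equal(sh$importance$predictor[1], "big")
  expect_gt(sh$importance$share[1], 0.5)
  # monotone increasing partial dependence of the planted driver
  pd <- dplyr::filter(sh$partial_dependence, predictor == "big")
  expect_gt(cor(pd$x, pd$shap, method = "spearman"), 0.9)
  sh2 <- shap_report(up, n_perm = 10, n_eval = 150, seed = 4)
  expect_identical(sh$importance, sh2$importance)
  expect_s3_class(ggplot2::autoplot(sh), "ggplot")
  expect_s3_class(plot_partial_dependence(sh), "ggplot")
})

test_that("site regression recovers an exact line and excludes outliers", {
  sites <- tibble::tibble(site = paste0("s", 1:8),
                          mat_c = seq(2, 23, by = 3))
  sites$f_bnfs <- 0.01 * sites$mat_c + 0.02
  # exact lines trigger summary.lm's perfect-fit warning by construction
  reg <- suppressWarnings(site_temperature_regression(sites))
  expect_equal(reg$slope, 0.01, tolerance = 1e-12)
  expect_equal(reg$intercept, 0.02, tolerance = 1e-12)
  expect_equal(reg$r_squared, 1)
  # planted outlier dragging the fit is excluded by name
  out <- dplyr::bind_rows(sites, tibble::tibble(site = "bad", mat_c = 20,
                                                f_bnfs = 0.02))
  reg_with <- site_temperature_regression(out)
  reg_without <- suppressWarnings(
    site_temperature_regression(out, exclude = "bad"))
  expect_lt(reg_with$r_squared, 1)
  expect_equal(reg_without$slope, 0.01, tolerance = 1e-12)
  expect_equal(reg_without$n_excluded, 1)
})

test_that("site regression drops non-invertible sites and guards
           degeneracy", {
  sites <- tibble::tibble(site = paste0("s", 1:6), mat_c = 1:6,
                          f_bnfs = 0.05, delta_p = c(1, 1, 1, 1, -2.5, 1))
  # constant response: perfect-fit warning is expected by construction
  reg <- suppressWarnings(site_temperature_regression(sites))
  expect_equal(reg$n_used, 5)
  expect_error(site_temperature_regression(
    tibble::tibble(site = c("a", "b", "c"), mat_c = 2, f_bnfs = 1:3 / 10)),
    "degenerate")
  expect_error(site_temperature_regression(sites[1:2, ]), "at least 3")
})

test_that("planted noisy slope is recovered within its confidence
           interval", {
  set.seed(37)
  n <- 30
  sites <- tibble::tibble(site = paste0("s", 1:n),
                          mat_c = runif(n, 0, 25))
  sites$f_bnfs <- 0.03 + 0.0032 * sites$mat_c + rnorm(n, 0, 0.008)
  reg <- site_temperature_regression(sites)
  fit <- attr(reg, "fit")
  ci <- confint(fit)["mat_c", ]
  expect_gt(0.0032, ci[1])
  expect_lt(0.0032, ci[2])
  expect_gt(reg$slope, 0)
})
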