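test_that("pathway-mix prior is the documented linear combination", {
  expect_equal(eps_u_prior_from_mix(1 / 3, 1 / 3, 1 / 3, 3, 6, 12), 7)
  expect_equal(eps_u_prior_from_mix(1, 0, 0), 2)
  expect_equal(eps_u_prior_from_mix(0, 0, 1), 9)
  # vectorised
  out <- eps_u_prior_from_mix(c(0.5, 0.2), c(0.3, 0.3), c(0.2, 0.5))
  expect_equal(out, c(0.5 * 2 + 0.3 * 4 + 0.2 * 9,
                      0.2 * 2 + 0.3 * 4 + 0.5 * 9))
})

test_that("pathway-mix prior enforces its input contracts", {
  expect_error(eps_u_prior_from_mix(0.5, 0.3, 0.3), "sum to 1")
  expect_error(eps_u_prior_from_mix(-0.1, 0.6, 0.5))
  expect_error(eps_u_prior_from_mix(1 / 3, 1 / 3, 1 / 3, 5, 4, 9),
               "eps_ecm > eps_am > eps_root")
})

test_that("recycled fraction matches hand arithmetic and bounds", {
  # gpp 1000, a (0.25, 0.30, 0.20), C:N (25, 300, 50), NRE (0.5, 0, 0.275)
  # N fluxes: 10, 1, 4; recycled = (5 + 0 + 1.1) / 15
  expect_equal(
    f_recycled_tot(1000, 0.25, 0.30, 0.20, 25, 300, 50, nre_leaf = 0.5),
    6.1 / 15
  )
  # zero NRE everywhere -> zero recycling
  expect_equal(
    f_recycled_tot(1000, 0.25, 0.30, 0.20, 25, 300, 50,
                   nre_leaf = 0, nre_root = 0), 0)
  expect_error(f_recycled_tot(0, 0.25, 0.30, 0.20, 25, 300, 50, 0.5),
               "positive")
})

test_that("deposition prior rescales by the recycled fraction", {
  expect_equal(f_depd_prior(0.10, 0), 0.10)
  expect_equal(f_depd_prior(0.10, 0.5), 0.20)
  # always at least the total-demand share
  frec <- seq(0, 0.8, by = 0.1)
  expect_true(all(f_depd_prior(0.10, frec) >= 0.10))
  expect_error(f_depd_prior(0.6, 0.5), "impossible")
  expect_error(f_depd_prior(0.1, 1), "< 1")
})

test_that("Monte-Carlo prior is deterministic and collapses at sd 0", {
  a <- mc_prior_f_bnfs(0.8, 4.8, 4.2, 0.5, 0.1, seed = 5)
  b <- mc_prior_f_bnfs(0.8, 4.8, 4.2, 0.5, 0.1, seed = 5)
  expect_identical(a, b)
  # eps_u_sd = 0: point prior at the closed-form solution (the pair below
  # is the exact forward image of f = 0.1, g = 0.1, eps = 4.2, ds = 4.8)
  dp <- forward_delta_p(0.1, 0.1, 4.2, 4.8)
  pt <- mc_prior_f_bnfs(dp, 4.8, 4.2, 0.5, f_depd = 0.1, seed = 1)
  p0 <- mc_prior_f_bnfs(dp, 4.8, 4.2, 0, f_depd = 0.1, seed = 1)
  expect_equal(p0$f_bnfs_mean, 0.1)
  expect_equal(p0$f_bnfs_sd, 0)
  expect_equal(p0$retention, 1)
  expect_gt(pt$f_bnfs_sd, 0)
})

test_that("Monte-Carlo prior matches a high-draw oracle within 3 SEs", {
  # oracle: independent huge sample of the same truncated push-forward
  set.seed(99)
  eps <- rnorm(2e5, 4.2, 0.5)
  f <- solve_f_bnfs(0.8, 4.8, eps, 0.1)
  f <- f[f >= 0 & f <= 0.9]
  mc <- mc_prior_f_bnfs(0.8, 4.8, 4.2, 0.5, 0.1, n_draws = 4000, seed = 3)
  se <- sd(f) / sqrt(4000 * mc$retention)
  expect_lt(abs(mc$f_bnfs_mean - mean(f)), 3 * se)
})

test_that("Monte-Carlo prior mean decreases with eps_u_mean (normal regime)",
{
  means <- vapply(c(3.0, 3.5, 4.0, 4.5), function(m)
    mc_prior_f_bnfs(0.8, 4.8, m, 0.3, 0.1, seed = 4)$f_bnfs_mean,
    numeric(1))
  # df/d eps_u = (1 - f - g)/(delta_bnf - delta_s + eps_u) < 0 here
  expect_true(all(diff(means) < 0))
})

test_that("Monte-Carlo prior refuses invalid pairs and flags degeneracy", {
  expect_error(mc_prior_f_bnfs(-2.5, 4.8, 4.2, 0.5), "check_validity")
  # a pair whose physical window retains almost no draws: plant far above
  # soil forces f < 0 for nearly every eps draw
  expect_warning(
    out <- mc_prior_f_bnfs(9.5, 4.8, 0.5, 0.05, 0, n_draws = 2000,
                           seed = 8),
    "retention"
  )
  expect_true(is.na(out$f_bnfs_mean))
})

test_that("build_priors appends finite priors for valid cells", {
  grid <- small_experiment()
  pg <- build_priors(grid, default_config(), seed = 2)
  expect_true(all(c("prior_f_bnfs_mean", "prior_f_bnfs_sd",
                    "prior_f_depd_mean", "prior_f_depd_sd",
                    "prior_eps_u_mean", "prior_eps_u_sd") %in% names(pg)))
  ok <- check_validity(grid$delta_p, grid$delta_s,
                       pg$prior_eps_u_mean)$valid
  expect_true(all(is.finite(pg$prior_f_bnfs_mean[ok])))
  expect_true(all(pg$prior_f_bnfs_sd[ok] > 0))
  # deposition prior exceeds the total-demand share everywhere
  expect_true(all(pg$prior_f_depd_mean >= default_config()$priors$f_depd_tot))
})
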