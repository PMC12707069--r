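test_that("observation operator agrees with the forward model", {
  tu <- random_valid_tuples(50, seed = 31)
  state <- cbind(tu$f, tu$g, tu$eps, tu$ds)
  pred <- observation_operator(state)
  expect_equal(unname(pred[, 1]), forward_delta_p(tu$f, tu$g, tu$eps, tu$ds))
  expect_equal(unname(pred[, 2]), tu$ds)
})

test_that("zero-spread ensembles pass through the analysis unchanged", {
  state <- matrix(rep(c(0.1, 0.1, 4, 5), each = 50), ncol = 4)
  pred <- observation_operator(state)
  set.seed(1)
  out <- enkf_analysis(state, pred, c(0.8, 4.8), c(0.5, 0.5))
  expect_equal(out, state)
})

test_that("uninformative observations leave the ensemble ~unchanged", {
  set.seed(2)
  state <- cbind(rnorm(2000, 0.1, 0.02), rnorm(2000, 0.1, 0.02),
                 rnorm(2000, 4, 0.5), rnorm(2000, 5, 0.5))
  pred <- observation_operator(state)
  out <- enkf_analysis(state, pred, c(0.8, 4.8), c(1e6, 1e6))
  expect_lt(max(abs(colMeans(out) - colMeans(state))), 1e-3)
  expect_lt(max(abs(apply(out, 2, sd) - apply(state, 2, sd))), 1e-3)
})

test_that("analysis matches the conjugate normal-normal posterior", {
  # scalar linear-Gaussian toy: x ~ N(1, 2^2), y = x + e, e ~ N(0, 1),
  # observed y = 3. Conjugate posterior: mean 2.6, var 0.8.
  n <- 1000
  reps <- 30
  mu_post <- 1 + 4 / (4 + 1) * (3 - 1)
  var_post <- 4 * 1 / (4 + 1)
  ms <- vs <- numeric(reps)
  set.seed(10)
  for (r in seq_len(reps)) {
    x <- matrix(rnorm(n, 1, 2), ncol = 1)
    out <- enkf_analysis(x, x, obs = 3, obs_sd = 1)
    ms[r] <- mean(out)
    vs[r] <- var(out[, 1])
  }
  se_m <- sd(ms) / sqrt(reps)
  se_v <- sd(vs) / sqrt(reps)
  expect_lt(abs(mean(ms) - mu_post), 3 * se_m)
  expect_lt(abs(mean(vs) - var_post), 3 * se_v)
})

test_that("multiple-data-assimilation passes reproduce the single full
           update in the linear-Gaussian limit", {
  # same scalar toy; k inflated passes must equal one full-strength pass
  n <- 4000
  mu_post <- 2.6
  set.seed(11)
  x <- matrix(rnorm(n, 1, 2), ncol = 1)
  k <- 4
  for (it in seq_len(k)) {
    x <- enkf_analysis(x, x, obs = 3, obs_sd = 1, inflation = k)
  }
  expect_lt(abs(mean(x) - mu_post), 0.15)
  expect_lt(abs(var(x[, 1]) - 0.8), 0.15)
})

test_that("invert_cell recovers self-consistent data given tight noise", {
  co <- isotope_constants()
  f <- 0.12; g <- 0.1; eps <- 3.5; ds <- 6.0
  dp <- forward_delta_p(f, g, eps, ds, co)
  prior <- list(f_bnfs_mean = 0.2, f_bnfs_sd = 0.08,
                f_depd_mean = 0.1, f_depd_sd = 0.02,
                eps_u_mean = 3.5, eps_u_sd = 0.5)
  post <- invert_cell(dp, ds, 0.01, 0.01, prior, co,
                      enkf_config(seed = 5))
  expect_true(post$valid)
  # observations pin delta_p and delta_s almost exactly, but two
  # observations cannot fully separate f from eps: with the mass balance
  # pinned, the residual f error is bounded by the eps posterior
  # uncertainty scaled by (1 - f - g) / |delta_bnf - delta_s + eps|
  bound <- 3 * post$eps_u_sd * (1 - f - g) /
    abs(co$delta_bnf - ds + eps)
  expect_lt(post$eps_u_sd, 0.5)    # so the bound is not vacuous
  expect_lt(abs(post$f_bnfs - f), max(bound, 0.02))
  expect_lt(abs(post$delta_s_state - ds), 0.02)
  expect_lt(post$f_bnfs_sd, prior$f_bnfs_sd)
})

test_that("invert_cell is bit-identical under a fixed seed", {
  prior <- list(f_bnfs_mean = 0.1, f_bnfs_sd = 0.05,
                f_depd_mean = 0.1, f_depd_sd = 0.05,
                eps_u_mean = 4, eps_u_sd = 1)
  cfg <- enkf_config(n_ensemble = 200, n_repeats = 3, seed = 42)
  a <- invert_cell(0.8, 4.8, 0.5, 0.5, prior, config = cfg)
  b <- invert_cell(0.8, 4.8, 0.5, 0.5, prior, config = cfg)
  expect_identical(a, b)
  c2 <- invert_cell(0.8, 4.8, 0.5, 0.5, prior,
                    config = enkf_config(n_ensemble = 200, n_repeats = 3,
                                         seed = 43))
  expect_false(identical(a$f_bnfs, c2$f_bnfs))
})

test_that("posterior obeys the physical constraints", {
  # data pulling f negative: plant above soil with weak fractionation
  prior <- list(f_bnfs_mean = 0.02, f_bnfs_sd = 0.05,
                f_depd_mean = 0.05, f_depd_sd = 0.05,
                eps_u_mean = 0.5, eps_u_sd = 0.3)
  post <- invert_cell(5.6, 4.8, 0.2, 0.2, prior,
                      config = enkf_config(n_ensemble = 300, n_repeats = 2,
                                           seed = 9))
  expect_gte(post$f_bnfs, 0)
  expect_gte(post$f_depd, 0)
  expect_gte(post$eps_u, 0)
  expect_lte(post$f_bnfs + post$f_depd, 1 + 1e-12)
})

test_that("invalid pairs carry their prior and valid = FALSE", {
  prior <- list(f_bnfs_mean = 0.1, f_bnfs_sd = 0.05,
                f_depd_mean = 0.1, f_depd_sd = 0.05,
                eps_u_mean = 4, eps_u_sd = 1)
  post <- invert_cell(-2.5, 4.8, 0.5, 0.5, prior)
  expect_false(post$valid)
  expect_equal(post$f_bnfs, prior$f_bnfs_mean)
  expect_equal(post$repeats, 0L)
})

test_that("invert_grid checks its schema and respects the mask", {
  grid <- small_experiment()
  expect_error(invert_grid(dplyr::select(grid, -"delta_p")),
               "missing columns")
  pg <- build_priors(grid[1:6, ], default_config(), seed = 2)
  pg$mask <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  post <- invert_grid(pg, config = enkf_config(n_ensemble = 150,
                                               n_repeats = 2,
                                               n_iterations = 2))
  expect_s3_class(post, "bnf_inversion")
  expect_equal(nrow(post), 4)
  expect_true(all(c("f_bnfs", "f_bnfs_sd", "valid") %in% names(post)))
})

test_that("posterior spread does not exceed prior spread on average", {
  grid <- small_experiment()[1:25, ]
  pg <- build_priors(grid, default_config(), seed = 2)
  post <- invert_grid(pg, config = enkf_config(n_ensemble = 300,
                                               n_repeats = 2,
                                               n_iterations = 2))
  v <- post$valid
  expect_lt(mean(post$f_bnfs_sd[v]), mean(post$prior_f_bnfs_sd[v]) + 1e-9)
  expect_lt(mean(post$eps_u_sd[v]), mean(post$prior_eps_u_sd[v]))
})
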