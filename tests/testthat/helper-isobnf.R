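# Random parameter tuples on the physical support whose forward plant
# delta15N passes the validity rule, for round-trip and oracle tests.
random_valid_tuples <- function(n, seed) {
  set.seed(seed)
  out <- NULL
  while (is.null(out) || nrow(out) < n) {
    f <- runif(2 * n, 0, 0.4)
    g <- runif(2 * n, 0, 0.3)
    eps <- runif(2 * n, 0.5, 6)
    ds <- runif(2 * n, 2, 8)
    dp <- forward_delta_p(f, g, eps, ds)
    ok <- check_validity(dp, ds, eps)
    keep <- ok$valid & !ok$warn_denominator
    out <- rbind(out, data.frame(f = f, g = g, eps = eps, ds = ds,
                                 dp = dp)[keep, ])
  }
  out[seq_len(n), ]
}

# Small synthetic experiment shared by several files (cheap, cached per
# session).
small_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- make_truth_grid(80, seed = 11)
      obs <- simulate_observations(truth, 0.5, 0.5, seed = 12)
      cache <<- dplyr::rename(
        obs, f_bnfs_true = f_bnfs, f_depd_true = f_depd,
        eps_u_true = eps_u, delta_p_true = delta_p,
        delta_s_true = delta_s) |>
        dplyr::rename(delta_p = delta_p_obs, delta_s = delta_s_obs)
    }
    cache
  }
})
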