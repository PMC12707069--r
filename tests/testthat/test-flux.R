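test_that("external demand matches hand arithmetic", {
  # gpp 1000, only wood: 1000 * 0.3 / 50 = 6.0 with zero NRE
  expect_equal(external_n_demand(1000, 0, 0.3, 0, 25, 50, 50,
                                 nre_leaf = 0), 6)
  # full example: leaf 10 * 0.5 + wood 1 + root 4 * 0.725
  expect_equal(
    external_n_demand(1000, 0.25, 0.30, 0.20, 25, 300, 50, nre_leaf = 0.5),
    10 * 0.5 + 1 + 4 * 0.725)
  # linear in GPP
  d1 <- external_n_demand(500, 0.25, 0.30, 0.20, 25, 300, 50, 0.5)
  d2 <- external_n_demand(1000, 0.25, 0.30, 0.20, 25, 300, 50, 0.5)
  expect_equal(2 * d1, d2)
  expect_error(external_n_demand(1000, 0.5, 0.4, 0.3, 25, 300, 50, 0.5))
})

test_that("total-BNF fraction flags but does not alter values above 1", {
  expect_warning(out <- f_bnf_total(c(0.3, 0.9), c(0.6, 0.6)), "flagged")
  expect_equal(as.numeric(out), c(0.5, 1.5))
  expect_equal(attr(out, "flagged"), c(FALSE, TRUE))
  expect_error(f_bnf_total(0.5, 0), "positive")
})

test_that("natural mask blanks managed cells only", {
  out <- apply_natural_mask(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(out, c(1, NA, 3))
})

test_that("uniform unit flux aggregates to area x 1e-12 Tg exactly", {
  area <- c(2e10, 3e10, 5e10)
  lat <- c(10, 40, 70)
  out <- aggregate_totals(rep(1, 3), area, lat)
  expect_equal(out$total_tg[out$band == "global"], sum(area) * 1e-12)
  expect_equal(out$total_tg[out$band == "30S-30N"], 2e10 * 1e-12)
  expect_equal(out$total_tg[out$band == "60N-90N"], 5e10 * 1e-12)
})

test_that("band totals partition the globe and sum to the global total", {
  set.seed(21)
  n <- 400
  lat <- runif(n, -90, 90)
  flux <- runif(n, 0, 2)
  area <- runif(n, 1e9, 1e11)
  out <- aggregate_totals(flux, area, lat)
  bands <- dplyr::filter(out, band != "global")
  expect_equal(sum(bands$n_cells), n)       # every cell in exactly one band
  expect_equal(sum(bands$total_tg),
               out$total_tg[out$band == "global"])
  expect_equal(out$total_tg[out$band == "global"],
               sum(flux * area) * 1e-12)
})

test_that("aggregation is invariant under cell permutation", {
  set.seed(22)
  n <- 100
  lat <- runif(n, -90, 90); flux <- runif(n); area <- runif(n, 1e9, 1e10)
  p <- sample.int(n)
  expect_equal(aggregate_totals(flux, area, lat),
               aggregate_totals(flux[p], area[p], lat[p]))
})

test_that("masked cells drop out of the totals", {
  flux <- c(1, NA, 1)
  out <- aggregate_totals(flux, rep(1e10, 3), c(0, 0, 0))
  expect_equal(out$total_tg[out$band == "global"], 2e10 * 1e-12)
  expect_equal(out$n_cells[out$band == "30S-30N"], 2)
})

# flux accounting operates on the (here: true) fixation parameters
flux_grid <- function() {
  dplyr::mutate(small_experiment(),
                f_bnfs = f_bnfs_true, f_depd = f_depd_true,
                eps_u = eps_u_true)
}

test_that("bnf_fluxes preserves the beta_s identity to 1e-12 relative", {
  grid <- flux_grid()
  grid$natural <- TRUE                 # keep every cell for the identity
  fl <- bnf_fluxes(grid)
  uncapped <- !is.na(fl$grid$f_bnf_t) & fl$grid$f_bnf_t < 1
  rel <- abs(fl$grid$bnf_total * fl$grid$beta_s -
               fl$grid$bnf_symbiotic)[uncapped] /
    pmax(abs(fl$grid$bnf_symbiotic[uncapped]), 1e-300)
  expect_lt(max(rel), 1e-12)
  expect_s3_class(fl, "bnf_fluxes")
  expect_error(bnf_fluxes(dplyr::select(grid, -"beta_s")),
               "missing columns")
})

test_that("bnf_fluxes respects the natural mask", {
  grid <- flux_grid()
  fl_all <- bnf_fluxes(dplyr::mutate(grid, natural = TRUE))
  fl_masked <- bnf_fluxes(grid)
  g_all <- fl_all$totals$total_tg[fl_all$totals$band == "global" &
                                    fl_all$totals$flux == "symbiotic"]
  g_masked <- fl_masked$totals$total_tg[fl_masked$totals$band == "global" &
                                          fl_masked$totals$flux ==
                                          "symbiotic"]
  expect_true(any(!grid$natural))
  expect_lt(g_masked, g_all)
})

test_that("transient adjustment is null at zero shift and increases BNF
           under the observed plant-delta15N decline", {
  # self-consistent (noise-free) grid so the zero-shift re-solve is exact
  grid <- dplyr::mutate(flux_grid(),
                        delta_p = delta_p_true, delta_s = delta_s_true)
  tr0 <- transient_adjustment(grid, shift = 0)
  expect_equal(max(abs(tr0$totals$delta_tg)), 0)
  tr <- transient_adjustment(grid, shift = -1.6)
  d <- tr$totals$delta_tg[tr$totals$band == "global"]
  expect_true(all(d > 0))
  # opposite shift moves totals the other way
  tr_up <- transient_adjustment(grid, shift = +1.6)
  d_up <- tr_up$totals$delta_tg[tr_up$totals$band == "global"]
  expect_true(all(d_up < 0))
})

test_that("tidiers and plots for fluxes work", {
  fl <- bnf_fluxes(flux_grid())
  td <- tidy(fl)
  expect_true(all(c("band", "total_tg", "flux") %in% names(td)))
  gl <- glance(fl)
  expect_equal(nrow(gl), 1)
  expect_true(gl$global_total_tg >= gl$global_symbiotic_tg)
  p <- ggplot2::autoplot(fl)
  expect_s3_class(p, "ggplot")
})
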