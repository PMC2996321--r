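test_that("Fano factor is ~1 for Poisson spiking at every window length", {
  r <- poisson_raster(59, 0.02, 100000, seed = 21)
  fr <- fano_factor(r, T_list = c(2, 5, 20, 100, 500))
  expect_true(all(abs(fr$F - 1) < 0.15))
})

test_that("Fano factor vanishes for a periodic train at commensurate windows", {
  r <- spike_raster(seq(0.5, 9999.5, by = 10), rep(1L, 1000), n_units = 1)
  fr <- fano_factor(r, T_list = c(10, 50, 100))
  expect_true(all(fr$F < 1e-12))
})

test_that("Fano factor at the native resolution approaches one minus the occupancy", {
  # binary counts: distinct integer spike times, one count per step at most
  set.seed(4)
  tt <- sort(sample.int(20000, 6000))
  r <- spike_raster(tt, sample.int(10, 6000, TRUE), n_units = 10)
  fr <- fano_factor(r, T_list = 1)
  occupancy <- 6000 / 20000
  expect_lt(abs(fr$F[1] - (1 - occupancy)), 0.02)
})

test_that("critical cascades give a Fano power law with positive exponent", {
  # the power law holds over the avalanche-relevant window range; at very
  # large windows cascade independence flattens the curve
  r <- branching_raster(59, 1, n_cascades = 4000, seed = 9)
  fr <- fano_factor(r, T_list = 10^seq(0.3, 3.3, length.out = 12),
                    fit_range = c(2, 300))
  expect_gt(fr$exponent_alpha, 0.3)
  # log-log linearity over the fitted range
  sel <- fr$T_list >= 2 & fr$T_list <= 300
  f <- stats::lm.fit(cbind(1, log10(fr$T_list[sel])), log10(fr$F[sel]))
  r2 <- 1 - sum(f$residuals^2) /
    sum((log10(fr$F[sel]) - mean(log10(fr$F[sel])))^2)
  expect_gt(r2, 0.8)
})

test_that("scaling collapse is exact for a single threshold and tight for Poisson onsets", {
  set.seed(6)
  r <- poisson_raster(30, 0.002, 60000)
  one <- scaling_function_collapse(r, s_list = 1, time_bin = 1)
  expect_equal(one$collapse_score, 0)
  # thinning a Poisson process leaves it Poisson: rescaled intervals collapse
  sc <- scaling_function_collapse(r, s_list = c(1, 2), time_bin = 1)
  expect_lt(sc$collapse_score, 0.12)
  expect_true(all(diff(sc$lambda_s) <= 0))
  # rescaled intervals have unit mean by construction
  for (iv in sc$intervals) expect_lt(abs(mean(iv) - 1), 0.15)
})

test_that("critical cascades collapse across size thresholds; bursty rate modulation does not", {
  r <- branching_raster(40, 1, n_cascades = 5000, seed = 14)
  sc <- scaling_function_collapse(r, s_list = c(1, 4, 16))
  expect_lt(sc$collapse_score, 0.12)
  # alternating fast/slow epochs -> interval mixture that cannot collapse
  set.seed(15)
  blocks <- lapply(0:39, function(k) {
    rate <- if (k %% 2 == 0) 2 else 0.01
    n <- rpois(1, rate * 500)
    sort(runif(n, k * 500, (k + 1) * 500))
  })
  tt <- sort(unlist(blocks))
  rb <- spike_raster(tt, sample.int(10, length(tt), TRUE), n_units = 10)
  scb <- scaling_function_collapse(rb, s_list = c(1, 3), time_bin = 3,
                                   min_count = 30)
  expect_gt(scb$collapse_score, sc$collapse_score)
  # too few qualifying avalanches is an error
  expect_error(scaling_function_collapse(r, s_list = 1e6), "need")
})

test_that("spatial subsampling at fraction one reproduces the full analysis", {
  r <- branching_raster(40, 1, n_cascades = 2500, seed = 5)
  full <- avalanche_analysis(r)
  sub <- spatial_subsample_test(r, fractions = 1)
  expect_equal(sub$summary$exponent, full$exponent)
  expect_equal(sub$summary$delta, full$delta)
  expect_error(spatial_subsample_test(r, fractions = 0.01), "fewer than 2")
})

test_that("critical cascades stay near-critical under subsampling and bin changes", {
  r <- branching_raster(59, 1, n_cascades = 8000, seed = 31)
  sub <- spatial_subsample_test(r, fractions = c(1, 0.75, 0.5), seed = 1)
  expect_true(all(abs(sub$summary$exponent - (-1.5)) < 0.25))
  bins <- bin_robustness_test(r, bin_multipliers = c(0.5, 1, 2))
  expect_equal(bins$summary$time_bin[2], bins$base_bin)
  expect_lt(max(bins$summary$delta) - min(bins$summary$delta), 0.6)
  expect_true(all(abs(bins$summary$exponent - (-1.5)) < 0.3))
  # enormous multiplier: single avalanche, clean degeneracy report
  deg <- bin_robustness_test(r, bin_multipliers = 1e9)
  expect_equal(deg$summary$n_avalanches, 1)
  expect_true(is.na(deg$summary$exponent))
})
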