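make_raster <- function(times, units = NULL, n_units = NULL) {
  if (is.null(units)) units <- rep(1L, length(times))
  spike_raster(times, units, n_units = n_units)
}

test_that("cross-correlogram peaks at zero lag for identical trains and is flat for independent ones", {
  tt <- seq(0, 500, by = 7)
  r <- spike_raster(c(tt, tt), c(rep(1, length(tt)), rep(2, length(tt))),
                    n_units = 2)
  cc <- mean_cross_correlation(r, max_lag = 50)
  expect_equal(which.max(cc$value), 1L)
  expect_true(all(cc$value >= 0))
  # independent Poisson trains: no dominant lag
  set.seed(1)
  rp <- poisson_raster(30, 0.05, 20000)
  ccp <- mean_cross_correlation(rp, max_lag = 100)
  expect_lt(max(ccp$value[-1]) / mean(ccp$value[-1]), 1.5)
  # needs two active units
  r1 <- spike_raster(c(1, 5, 9), c(1, 1, 1), n_units = 3)
  expect_error(mean_cross_correlation(r1), "2 units")
})

test_that("correlation cutoff captures the 99% area quantile", {
  flat <- data.frame(lag = 0:100, value = rep(1, 101))
  expect_equal(cc_cutoff(flat), 99)  # ~0.99 * 100
  spike0 <- data.frame(lag = 0:100, value = c(1, rep(0, 100)))
  expect_equal(cc_cutoff(spike0), 0)
  # exponential decay: cutoff ~ ln(100) / lambda
  lam <- 0.05
  ex <- data.frame(lag = 0:2000, value = exp(-lam * (0:2000)))
  expect_lt(abs(cc_cutoff(ex) - log(100) / lam), 3)
  expect_error(cc_cutoff(data.frame(lag = 0:3, value = rep(0, 4))), "zero area")
})

test_that("adaptive time bin is the mean inter-spike interval below the cutoff", {
  r <- spike_raster(c(0, 1, 2, 3, 0.5, 1.5), c(1, 1, 1, 1, 2, 2), n_units = 2)
  # pooled 0, .5, 1, 1.5, 2, 3: mean gap ~ 0.6 with generous cutoff
  bin <- compute_time_bin(r, max_lag = 10)
  expect_equal(bin, mean(diff(sort(r$events$time))))
  # long intervals beyond the cutoff are sorted out
  tt <- c(seq(0, 50, by = 1), 400, 401, 800, 801)
  r2 <- spike_raster(c(tt, tt + 0.2), rep(1:2, each = length(tt)), n_units = 2)
  bin2 <- compute_time_bin(r2, max_lag = 50)
  expect_lt(bin2, 2)
  # homogeneous Poisson pooled rate r -> bin ~ 1/(n*r)
  set.seed(3)
  rp <- poisson_raster(5, 0.04, 20000)
  bin3 <- compute_time_bin(rp, max_lag = 1000)
  expect_lt(abs(bin3 - 1 / 0.2) / (1 / 0.2), 0.15)
})

test_that("avalanche detection splits at gaps of at least one bin", {
  r <- make_raster(c(0, 1, 2, 10, 11))
  av <- detect_avalanches(r, 3)
  expect_equal(av$sizes, c(3L, 2L))
  expect_equal(av$durations, c(2, 1))
  expect_equal(av$inter_avalanche_intervals, 8)
  # single spike
  av1 <- detect_avalanches(make_raster(5), 2)
  expect_equal(av1$sizes, 1L)
  expect_equal(av1$durations, 0)
  # bin larger than the whole recording: one avalanche
  av2 <- detect_avalanches(make_raster(c(1, 4, 9, 20)), 100)
  expect_equal(av2$sizes, 4L)
  # empty raster
  av0 <- detect_avalanches(spike_raster(numeric(0), integer(0), n_units = 2), 1)
  expect_length(av0$sizes, 0)
})

test_that("avalanche sizes conserve spikes and shrink in number with larger bins", {
  set.seed(10)
  for (i in 1:100) {
    n <- sample(5:200, 1)
    tt <- sort(runif(n, 0, 500))
    bin <- runif(1, 0.5, 30)
    r <- make_raster(tt)
    av <- detect_avalanches(r, bin)
    expect_equal(sum(av$sizes), n)
    expect_true(all(av$inter_avalanche_intervals >= bin))
    # oracle equivalence
    expect_equal(av$sizes, brute_force_avalanches(tt, bin))
  }
  # monotonicity in the bin
  set.seed(11)
  tt <- sort(runif(300, 0, 1000))
  r <- make_raster(tt)
  n_av <- sapply(c(0.5, 1, 2, 5, 10, 50), function(b)
    length(detect_avalanches(r, b)$sizes))
  expect_true(all(diff(n_av) <= 0))
})

test_that("size distribution is a normalised probability over observed sizes", {
  d <- size_distribution(c(1L, 1L, 2L))
  expect_equal(d$sizes_axis, c(1, 2))
  expect_equal(d$prob, c(2 / 3, 1 / 3))
  d2 <- size_distribution(rep(7L, 5))
  expect_equal(d2$prob, 1)
  set.seed(2)
  d3 <- size_distribution(sample(1:20, 500, replace = TRUE))
  expect_equal(sum(d3$prob), 1)
})

test_that("log-log regression recovers exact power laws", {
  s <- 1:100
  for (expn in c(-1.5, -1)) {
    p <- s^expn / sum(s^expn)
    fit <- fit_power_law(s, p)
    expect_equal(fit$exponent, expn, tolerance = 1e-9)
    expect_equal(fit$fit_range, c(1, 100))
  }
  expect_error(fit_power_law(c(1, 2), c(0.5, 0.5)), "3 distinct")
  # explicit fit range is honoured
  p <- s^-1.5; p <- p / sum(p)
  fit2 <- fit_power_law(s, p, fit_range = c(5, 50))
  expect_equal(fit2$fit_range, c(5, 50))
  expect_equal(fit2$exponent, -1.5, tolerance = 1e-9)
})

test_that("critical branching cascades give the -1.5 size exponent", {
  r <- branching_raster(30, sigma = 1, n_cascades = 6000, seed = 13)
  fit <- avalanche_analysis(r)
  expect_gt(fit$n_avalanches, 5000)
  expect_lt(abs(fit$exponent - (-1.5)), 0.12)
})

test_that("the deviation measure is zero on a power law, positive with tail mass, negative with truncation", {
  s <- 1:200
  p <- s^-1.5 / sum(s^-1.5)
  fit <- fit_power_law(s, p)
  expect_lt(abs(delta_measure(s, p, fit)), 1e-9)
  # bump of large avalanches
  p_bump <- p
  p_bump[s >= 150] <- p_bump[s >= 150] * 8
  p_bump <- p_bump / sum(p_bump)
  fit_b <- fit_power_law(s, p_bump)
  expect_gt(delta_measure(s, p_bump, fit_b), 0.05)
  # truncated tail
  keep <- s <= 60
  p_tr <- s[keep]^-1.5 * exp(-(s[keep]) / 15)
  p_tr <- p_tr / sum(p_tr)
  fit_t <- fit_power_law(s[keep], p_tr)
  expect_lt(delta_measure(s[keep], p_tr, fit_t), -0.05)
})

test_that("tail mass moves the deviation monotonically", {
  s <- 1:200
  base <- s^-1.5
  deltas <- sapply(c(0.25, 1, 4), function(boost) {
    p <- base
    p[s >= 100] <- p[s >= 100] * boost
    p <- p / sum(p)
    fit <- fit_power_law(s, p)
    delta_measure(s, p, fit)
  })
  expect_true(all(diff(deltas) > 0))
})

test_that("state classification follows the heuristic thresholds", {
  expect_equal(classify_state(0), "critical")
  expect_equal(classify_state(0.5), "supercritical")
  expect_equal(classify_state(-0.5), "subcritical")
  expect_equal(classify_state(0.15, thresholds = c(-0.2, 0.2)), "critical")
  expect_error(classify_state(0, thresholds = c(0.1, 0.2)))
})

test_that("the analysis pipeline reports degenerate inputs instead of failing", {
  # a raster whose spikes form one giant avalanche
  r <- spike_raster(c(0:50, 0:50 + 0.3), rep(1:2, each = 51), n_units = 2)
  out <- avalanche_analysis(r, time_bin = 1000)
  expect_s3_class(out, "avalanche_fit")
  expect_equal(out$n_avalanches, 1L)
  expect_true(is.na(out$exponent))
  expect_match(out$note, "distinct")
})
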