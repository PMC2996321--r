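#' Mean cross-correlogram of all unit pairs
#'
#' Average over all ordered unit pairs of their spike-train cross-correlogram
#' on lags `[0, max_lag]`, computed on binarised trains at `lag_resolution`.
#' Used to bound the inter-spike intervals entering the adaptive time bin
#' (see [cc_cutoff()], [compute_time_bin()]).
#'
#' Implementation: the pooled-count correlogram is obtained by FFT and the
#' per-unit autocorrelograms (computed sparsely from spike-time differences)
#' are subtracted, which equals the sum over ordered pairs of cross products.
#'
#' @param raster a [spike_raster()] with spikes on at least two units.
#' @param max_lag largest lag (time units).
#' @param lag_resolution correlogram bin width; defaults to the native
#'   resolution (1 time unit).
#' @return A data frame (class `cc_curve`) with columns `lag` and `value`.
#' @export
mean_cross_correlation <- function(raster, max_lag = 1000,
                                   lag_resolution = 1) {
  ev <- raster$events
  active <- unique(ev$unit)
  if (length(active) < 2L)
    stop("mean cross-correlation requires spikes on at least 2 units",
         call. = FALSE)
  res <- lag_resolution
  tb <- as.integer(floor((ev$time - min(ev$time)) / res))
  Tn <- max(tb) + 1L
  L <- as.integer(min(floor(max_lag / res), Tn - 1L))
  S <- tabulate(tb + 1L, nbins = Tn)
  m <- stats::nextn(Tn + L + 1L)
  fS <- stats::fft(c(S, rep(0, m - Tn)))
  pooled <- Re(stats::fft(fS * Conj(fS), inverse = TRUE))[1:(L + 1L)] / m
  # one-sided per-unit autocorrelograms; the pooled correlogram at lag l
  # already sums C_ij(l) over ALL ordered unit pairs (i, j), so the
  # cross-only part is pooled minus the same-unit terms
  auto <- numeric(L + 1L)
  for (u in active) {
    tu <- sort(tb[ev$unit == u])
    mu <- length(tu)
    cnt <- tabulate(tu - tu[1] + 1L)
    cnt <- cnt[cnt > 0]
    auto[1] <- auto[1] + sum(cnt^2)  # lag-0 self products incl. same-bin pairs
    k <- 1L
    while (k < mu) {
      dd <- tu[(1L + k):mu] - tu[1L:(mu - k)]
      if (min(dd) > L) break
      dd <- dd[dd <= L & dd > 0]
      auto <- auto + tabulate(dd + 1L, nbins = L + 1L)
      k <- k + 1L
    }
  }
  cross <- pmax(0, pooled - auto) /
    (length(active) * (length(active) - 1L))
  out <- data.frame(lag = (0:L) * res, value = cross)
  class(out) <- c("cc_curve", "data.frame")
  out
}

#' Integration cutoff of a correlation curve
#'
#' The smallest lag below which `q` (default 99%) of the area under the curve
#' lies. Intervals longer than this cutoff are regarded as belonging to a
#' slower timescale and are excluded from the adaptive time bin.
#'
#' @param curve a `cc_curve` (or any data frame with `lag` and `value`).
#' @param q area quantile.
#' @return The cutoff lag (scalar).
#' @export
cc_cutoff <- function(curve, q = 0.99) {
  tot <- sum(curve$value)
  if (!is.finite(tot) || tot <= 0)
    stop("correlation curve has zero area", call. = FALSE)
  curve$lag[which(cumsum(curve$value) >= q * tot)[1]]
}

#' Adaptive avalanche time bin
#'
#' The time bin is the mean interval between consecutive spikes of the pooled
#' (all-unit) spike train, excluding intervals longer than the 99%-area
#' cutoff of the mean cross-correlogram, so that pauses between bursts on a
#' longer timescale do not distort the statistics.
#'
#' @param raster a [spike_raster()] with at least 2 spikes.
#' @param max_lag largest lag of the underlying correlogram.
#' @param lag_resolution correlogram resolution.
#' @return The time bin (scalar, same units as the raster).
#' @export
compute_time_bin <- function(raster, max_lag = 1000, lag_resolution = 1) {
  pt <- raster$events$time  # already sorted
  if (length(pt) < 2L) stop("need at least 2 spikes", call. = FALSE)
  isi <- diff(pt)
  cut <- cc_cutoff(mean_cross_correlation(raster, max_lag, lag_resolution))
  keep <- isi <= cut
  if (!any(keep))
    stop(sprintf(paste0("no inter-spike interval survives the exclusion ",
                        "(cutoff %.3g, shortest interval %.3g); the raster ",
                        "is too sparse for an adaptive bin"),
                 cut, min(isi)), call. = FALSE)
  mean(isi[keep])
}

#' Extract avalanches from a raster
#'
#' An avalanche is a maximal run of pooled spikes in which consecutive spikes
#' are separated by less than the time bin; whenever the system is silent for
#' at least one time bin the avalanche ends and the next spike opens a new
#' one. Every spike belongs to exactly one avalanche.
#'
#' @param raster a [spike_raster()].
#' @param time_bin the bin from [compute_time_bin()] (or any positive value).
#' @return An object of class `avalanche_set`: `sizes` (spikes per
#'   avalanche), `durations` (last minus first spike time), `start_times`,
#'   `end_times`, `inter_avalanche_intervals` (silent gaps between
#'   consecutive avalanches, each at least `time_bin`), `time_bin`,
#'   `n_spikes`, `duration` (of the raster).
#' @export
detect_avalanches <- function(raster, time_bin) {
  stopifnot(time_bin > 0)
  pt <- raster$events$time
  if (!length(pt)) {
    av <- list(sizes = integer(0), durations = numeric(0),
               start_times = numeric(0), end_times = numeric(0),
               inter_avalanche_intervals = numeric(0),
               time_bin = time_bin, n_spikes = 0L, duration = raster$duration)
    class(av) <- "avalanche_set"
    return(av)
  }
  gaps <- diff(pt)
  brk <- which(gaps >= time_bin)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(pt))
  av <- list(sizes = as.integer(ends - starts + 1L),
             durations = pt[ends] - pt[starts],
             start_times = pt[starts],
             end_times = pt[ends],
             inter_avalanche_intervals =
               if (length(starts) > 1L) pt[starts[-1]] - pt[ends[-length(ends)]]
               else numeric(0),
             time_bin = time_bin,
             n_spikes = length(pt),
             duration = raster$duration)
  class(av) <- "avalanche_set"
  av
}

#' @export
print.avalanche_set <- function(x, ...) {
  cat(sprintf("avalanche_set: %d avalanches from %d spikes (time bin %.3g)\n",
              length(x$sizes), x$n_spikes, x$time_bin))
  if (length(x$sizes))
    cat(sprintf("  sizes: median %g, max %g; mean inter-avalanche gap %.3g\n",
                stats::median(x$sizes), max(x$sizes),
                mean(x$inter_avalanche_intervals)))
  invisible(x)
}

#' Empirical avalanche-size distribution
#'
#' @param av an [detect_avalanches()] result (or an integer vector of sizes).
#' @return `list(sizes_axis, prob)` with `sum(prob) == 1` over observed
#'   sizes.
#' @export
size_distribution <- function(av) {
  sizes <- if (inherits(av, "avalanche_set")) av$sizes else as.integer(av)
  if (!length(sizes)) stop("no avalanches", call. = FALSE)
  tb <- table(sizes)
  list(sizes_axis = as.numeric(names(tb)),
       prob = as.numeric(tb) / sum(tb))
}

#' Log-log regression of the avalanche-size distribution
#'
#' Ordinary least squares through `(log10 s, log10 P(s))` over the left
#' linear region of the distribution. By default the fit starts at the
#' smallest observed size and extends to the largest size for which the
#' expanding-window regression keeps `R^2 >= r2_min`, operationalising "to
#' the end of the linear behaviour"; both ends can be overridden via
#' `fit_range`.
#'
#' @param sizes_axis,prob the empirical distribution from
#'   [size_distribution()].
#' @param fit_range optional `c(s_lo, s_hi)` fixing the fitted size range.
#' @param r2_min R-squared threshold of the expanding-window policy.
#' @return An object of class `powerlaw_fit`: `exponent` (the slope),
#'   `intercept`, `fit_range`, `r_squared`, `n_points`.
#' @export
fit_power_law <- function(sizes_axis, prob, fit_range = NULL, r2_min = 0.98) {
  o <- order(sizes_axis)
  s <- sizes_axis[o]; p <- prob[o]
  if (!is.null(fit_range)) {
    keep <- s >= fit_range[1] & s <= fit_range[2]
    s2 <- s[keep]; p2 <- p[keep]
    if (length(s2) < 3L)
      stop("fewer than 3 distinct sizes in the fit range", call. = FALSE)
    f <- stats::lm.fit(cbind(1, log10(s2)), log10(p2))
    kmax <- length(s2)
    rng <- range(s2)
  } else {
    if (length(s) < 3L)
      stop("fewer than 3 distinct sizes", call. = FALSE)
    ls <- log10(s); lp <- log10(p)
    kmax <- 3L
    for (k in 3:length(s)) {
      fk <- stats::lm.fit(cbind(1, ls[1:k]), lp[1:k])
      ss_tot <- sum((lp[1:k] - mean(lp[1:k]))^2)
      r2 <- if (ss_tot > 0) 1 - sum(fk$residuals^2) / ss_tot else 1
      if (r2 >= r2_min) kmax <- k else break
    }
    f <- stats::lm.fit(cbind(1, ls[1:kmax]), lp[1:kmax])
    rng <- c(s[1], s[kmax])
  }
  ss_tot <- sum((f$residuals + f$fitted.values - mean(f$fitted.values +
                                                       f$residuals))^2)
  fit <- list(exponent = unname(f$coefficients[2]),
              intercept = unname(f$coefficients[1]),
              fit_range = rng,
              r_squared = if (ss_tot > 0) 1 - sum(f$residuals^2) / ss_tot else 1,
              n_points = kmax)
  class(fit) <- "powerlaw_fit"
  fit
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("power-law fit: slope %.3f over sizes [%g, %g] (%d points, R^2 = %.3f)\n",
              x$exponent, x$fit_range[1], x$fit_range[2], x$n_points,
              x$r_squared))
  invisible(x)
}

#' Deviation from a power law
#'
#' The mean over all observed sizes of the log10 residual of the empirical
#' distribution from its left-anchored regression line. Excess probability
#' mass at large avalanches ("bump") gives a positive deviation, a truncated
#' tail a negative one, and an exact power law zero.
#'
#' @inheritParams fit_power_law
#' @param fit a [fit_power_law()] result computed on the same distribution.
#' @return The scalar deviation (log10 units).
#' @export
delta_measure <- function(sizes_axis, prob, fit) {
  pred <- fit$intercept + fit$exponent * log10(sizes_axis)
  mean(log10(prob) - pred)
}

#' Classify the dynamical state from the deviation measure
#'
#' @param delta deviation from [delta_measure()].
#' @param thresholds `c(lo, hi)` with `lo < 0 < hi`; the values are heuristic
#'   and configurable (defaults -0.1, 0.1, in log10 units).
#' @return One of `"subcritical"`, `"critical"`, `"supercritical"`.
#' @export
classify_state <- function(delta, thresholds = c(-0.1, 0.1)) {
  stopifnot(thresholds[1] < 0, thresholds[2] > 0)
  if (is.na(delta)) return(NA_character_)
  if (delta > thresholds[2]) "supercritical"
  else if (delta < thresholds[1]) "subcritical"
  else "critical"
}

#' Full avalanche analysis of a raster
#'
#' Convenience pipeline: adaptive time bin, avalanche extraction, size
#' distribution, power-law regression, deviation measure and state label.
#' Degenerate inputs (too few avalanches or distinct sizes for a fit) are
#' reported, not raised: the returned object then carries `NA` fit fields
#' and a diagnostic message.
#'
#' @param raster a [spike_raster()].
#' @param time_bin optional fixed bin; computed adaptively when `NULL`.
#' @param max_lag,lag_resolution passed to [compute_time_bin()].
#' @param fit_range,r2_min passed to [fit_power_law()].
#' @param thresholds passed to [classify_state()].
#' @return An object of class `avalanche_fit`: the avalanche set plus
#'   `sizes_axis`, `prob`, `exponent`, `intercept`, `fit_range`, `delta`,
#'   `label`, `time_bin`, `n_avalanches`, and `note` (diagnostic, or `NA`).
#' @export
avalanche_analysis <- function(raster, time_bin = NULL, max_lag = 1000,
                               lag_resolution = 1, fit_range = NULL,
                               r2_min = 0.98, thresholds = c(-0.1, 0.1)) {
  if (is.null(time_bin))
    time_bin <- compute_time_bin(raster, max_lag, lag_resolution)
  av <- detect_avalanches(raster, time_bin)
  out <- list(avalanches = av, time_bin = time_bin,
              n_avalanches = length(av$sizes),
              sizes_axis = NULL, prob = NULL,
              exponent = NA_real_, intercept = NA_real_,
              fit_range = c(NA_real_, NA_real_),
              delta = NA_real_, label = NA_character_, note = NA_character_)
  class(out) <- "avalanche_fit"
  if (!length(av$sizes)) {
    out$note <- "no avalanches"
    return(out)
  }
  dist <- size_distribution(av)
  out$sizes_axis <- dist$sizes_axis
  out$prob <- dist$prob
  fit <- tryCatch(fit_power_law(dist$sizes_axis, dist$prob, fit_range, r2_min),
                  error = function(e) conditionMessage(e))
  if (is.character(fit)) {
    out$note <- fit
    return(out)
  }
  out$exponent <- fit$exponent
  out$intercept <- fit$intercept
  out$fit_range <- fit$fit_range
  out$delta <- delta_measure(dist$sizes_axis, dist$prob, fit)
  out$label <- classify_state(out$delta, thresholds)
  out
}

#' @export
print.avalanche_fit <- function(x, ...) {
  cat(sprintf("avalanche analysis: bin %.3g, %d avalanches\n",
              x$time_bin, x$n_avalanches))
  if (!is.na(x$note)) {
    cat("  note:", x$note, "\n")
  } else {
    cat(sprintf("  exponent %.3f on [%g, %g], deviation %+.3f -> %s\n",
                x$exponent, x$fit_range[1], x$fit_range[2], x$delta, x$label))
  }
  invisible(x)
}

#' @export
plot.avalanche_fit <- function(x, ...) {
  if (is.null(x$sizes_axis)) stop("nothing to plot", call. = FALSE)
  graphics::plot(x$sizes_axis, x$prob, log = "xy",
                 xlab = "avalanche size s", ylab = "P(s)", pch = 1, ...)
  if (!is.na(x$exponent)) {
    s <- x$sizes_axis
    graphics::lines(s, 10^(x$intercept + x$exponent * log10(s)), lty = 2)
    graphics::legend("topright", bty = "n", legend = sprintf(
      "slope %.2f, deviation %+.2f (%s)", x$exponent, x$delta, x$label))
  }
  invisible(x)
}
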