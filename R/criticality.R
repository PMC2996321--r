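#' Spatial subsampling test for scale-free behaviour
#'
#' A genuinely scale-free system shows a power-law avalanche distribution
#' even when only a subset of the neurons (model) or electrodes (recording)
#' is observed. For each fraction a uniform random unit subset is retained
#' and the full analysis (adaptive bin, avalanches, regression, deviation) is
#' recomputed.
#'
#' @param raster a [spike_raster()].
#' @param fractions fractions of units to retain, each in `(0, 1]`.
#' @param seed optional seed for the unit sampling.
#' @param ... passed to [avalanche_analysis()].
#' @return A list with `fits` (one [avalanche_analysis()] result per
#'   fraction) and `summary` (data frame: fraction, n_units, time_bin,
#'   exponent, delta, label).
#' @export
spatial_subsample_test <- function(raster, fractions = c(1, 0.75, 0.5),
                                   seed = NULL, ...) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  if (!is.null(seed)) set.seed(seed)
  fits <- lapply(fractions, function(f) {
    k <- round(f * raster$n_units)
    if (k < 2L)
      stop(sprintf("fraction %g leaves fewer than 2 units", f), call. = FALSE)
    sub <- if (k == raster$n_units) raster
           else raster_subset(raster, sample.int(raster$n_units, k))
    avalanche_analysis(sub, ...)
  })
  summary <- data.frame(
    fraction = fractions,
    n_units = round(fractions * raster$n_units),
    time_bin = vapply(fits, `[[`, numeric(1), "time_bin"),
    exponent = vapply(fits, `[[`, numeric(1), "exponent"),
    delta = vapply(fits, `[[`, numeric(1), "delta"),
    label = vapply(fits, `[[`, character(1), "label"))
  list(fits = fits, summary = summary)
}

#' Time-bin robustness test
#'
#' Temporal scale-freeness: the avalanche distribution should show only minor
#' variations when the analysis is repeated with the time bin scaled by
#' different multipliers.
#'
#' @param raster a [spike_raster()].
#' @param bin_multipliers positive multipliers of the adaptive bin.
#' @param time_bin optional base bin; computed adaptively when `NULL`.
#' @param ... passed to [avalanche_analysis()].
#' @return A list with `base_bin`, `fits`, and a `summary` data frame
#'   (multiplier, time_bin, n_avalanches, exponent, delta, label).
#' @export
bin_robustness_test <- function(raster, bin_multipliers = c(0.5, 1, 2),
                                time_bin = NULL, ...) {
  stopifnot(all(bin_multipliers > 0))
  if (is.null(time_bin)) time_bin <- compute_time_bin(raster)
  fits <- lapply(bin_multipliers, function(m)
    avalanche_analysis(raster, time_bin = time_bin * m, ...))
  summary <- data.frame(
    multiplier = bin_multipliers,
    time_bin = time_bin * bin_multipliers,
    n_avalanches = vapply(fits, `[[`, numeric(1), "n_avalanches"),
    exponent = vapply(fits, `[[`, numeric(1), "exponent"),
    delta = vapply(fits, `[[`, numeric(1), "delta"),
    label = vapply(fits, `[[`, character(1), "label"))
  list(base_bin = time_bin, fits = fits, summary = summary)
}

#' Scaling-function collapse of inter-avalanche intervals
#'
#' For each minimum event size `s`, the onset-to-onset intervals between
#' consecutive avalanches of size at least `s` are collected and rescaled by
#' the rate `lambda_s` of such avalanches. If the system is scale-free the
#' rescaled interval distributions collapse onto a single curve. The quality
#' of the collapse is quantified as the maximum pairwise Kolmogorov-style
#' sup-distance between the rescaled empirical distribution functions (0 =
#' perfect collapse).
#'
#' @param raster a [spike_raster()].
#' @param s_list minimum avalanche sizes.
#' @param time_bin optional bin; computed adaptively when `NULL`.
#' @param min_count minimum number of qualifying avalanches per threshold.
#' @return An object of class `scaling_collapse`: `s_list`, `lambda_s`,
#'   `intervals` (list of rescaled intervals per threshold) and
#'   `collapse_score`.
#' @export
scaling_function_collapse <- function(raster, s_list = c(1, 2, 4),
                                      time_bin = NULL, min_count = 50) {
  if (is.null(time_bin)) time_bin <- compute_time_bin(raster)
  av <- detect_avalanches(raster, time_bin)
  s_list <- sort(s_list)
  lambda_s <- numeric(length(s_list))
  rescaled <- vector("list", length(s_list))
  for (i in seq_along(s_list)) {
    onsets <- av$start_times[av$sizes >= s_list[i]]
    if (length(onsets) < min_count)
      stop(sprintf("only %d avalanches of size >= %g (need %d)",
                   length(onsets), s_list[i], min_count), call. = FALSE)
    lambda_s[i] <- length(onsets) / av$duration
    rescaled[[i]] <- diff(onsets) * lambda_s[i]
  }
  score <- 0
  if (length(s_list) > 1L) {
    for (i in seq_along(s_list)[-1]) for (j in seq_len(i - 1L)) {
      grid <- sort(unique(c(rescaled[[i]], rescaled[[j]])))
      Fi <- stats::ecdf(rescaled[[i]])(grid)
      Fj <- stats::ecdf(rescaled[[j]])(grid)
      score <- max(score, max(abs(Fi - Fj)))
    }
  }
  out <- list(s_list = s_list, lambda_s = lambda_s, intervals = rescaled,
              collapse_score = score, time_bin = time_bin)
  class(out) <- "scaling_collapse"
  out
}

#' @export
print.scaling_collapse <- function(x, ...) {
  cat(sprintf("scaling-function collapse over s = {%s}: score %.4f\n",
              paste(x$s_list, collapse = ", "), x$collapse_score))
  cat(sprintf("  rates lambda_s: %s per time unit\n",
              paste(signif(x$lambda_s, 3), collapse = ", ")))
  invisible(x)
}

#' Fano factor of the pooled spike train
#'
#' Variance-to-mean ratio of pooled spike counts in disjoint windows of
#' length `T`, for a list of window lengths. A Poisson process has Fano
#' factor 1 at every `T`; a scale-free point process shows a power law
#' `F(T) ~ T^alpha` over a wide range of windows, whose exponent is
#' estimated by log-log regression over `fit_range`.
#'
#' @param raster a [spike_raster()].
#' @param T_list window lengths; default: 20 log-spaced values between the
#'   native resolution and `duration/10`.
#' @param fit_range `c(T_lo, T_hi)` for the exponent regression; defaults to
#'   `[10 * resolution, duration/20]`.
#' @param resolution native time resolution of the raster (1 for model
#'   steps).
#' @return An object of class `fano_result`: `T_list`, `F` (one value per
#'   window length; windows with zero mean count are dropped with a
#'   warning), `exponent_alpha`, `fit_range`.
#' @export
fano_factor <- function(raster, T_list = NULL, fit_range = NULL,
                        resolution = 1) {
  dur <- raster$duration
  if (is.null(T_list))
    T_list <- unique(10^seq(log10(resolution), log10(dur / 10), length.out = 20))
  stopifnot(all(T_list > 0), all(T_list <= dur / 10))
  tt <- raster$events$time - raster$t_start
  Fv <- rep(NA_real_, length(T_list))
  for (i in seq_along(T_list)) {
    Tw <- T_list[i]
    nw <- floor(dur / Tw)
    idx <- floor(tt / Tw) + 1
    idx <- idx[idx <= nw]
    counts <- tabulate(idx, nbins = nw)
    m <- mean(counts)
    if (m == 0) next
    Fv[i] <- stats::var(counts) / m
  }
  if (anyNA(Fv)) {
    warning(sprintf("%d window length(s) dropped (zero mean count)",
                    sum(is.na(Fv))))
    keep <- !is.na(Fv)
    T_list <- T_list[keep]; Fv <- Fv[keep]
  }
  if (is.null(fit_range)) fit_range <- c(10 * resolution, dur / 20)
  sel <- T_list >= fit_range[1] & T_list <= fit_range[2] & Fv > 0
  alpha <- if (sum(sel) >= 3) {
    unname(stats::lm.fit(cbind(1, log10(T_list[sel])),
                         log10(Fv[sel]))$coefficients[2])
  } else NA_real_
  out <- list(T_list = T_list, F = Fv, exponent_alpha = alpha,
              fit_range = fit_range)
  class(out) <- "fano_result"
  out
}

#' @export
print.fano_result <- function(x, ...) {
  cat(sprintf("Fano factor over %d window lengths [%g, %g]\n",
              length(x$T_list), min(x$T_list), max(x$T_list)))
  cat(sprintf("  F range [%.3g, %.3g]; power-law exponent %.3f on [%g, %g]\n",
              min(x$F), max(x$F), x$exponent_alpha,
              x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' @export
plot.fano_result <- function(x, ...) {
  graphics::plot(x$T_list, x$F, log = "xy", xlab = "window length T",
                 ylab = "Fano factor F(T)", pch = 1, ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}
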