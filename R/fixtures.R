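#' Homogeneous Poisson raster
#'
#' Independent homogeneous Poisson spike trains per unit: the null model for
#' a network without connectivity. Serves as the statistical reference for
#' the analysis stack (Fano factor 1, strongly sub-power-law avalanche
#' distribution, trivially collapsing inter-avalanche intervals).
#'
#' @param n_units number of units.
#' @param rate_per_unit expected spikes per unit per time unit.
#' @param duration recording length.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return A [spike_raster()] with continuous event times.
#' @export
poisson_raster <- function(n_units, rate_per_unit, duration, seed = NULL) {
  stopifnot(n_units >= 1, rate_per_unit > 0, duration > 0)
  if (!is.null(seed)) set.seed(seed)
  counts <- rpois(n_units, rate_per_unit * duration)
  unit <- rep(seq_len(n_units), counts)
  time <- runif(sum(counts), 0, duration)
  spike_raster(time, unit, n_units = n_units, duration = duration,
               time_unit = "steps", t_start = 0)
}

#' Branching-process raster (Galton-Watson cascades)
#'
#' Reference model for criticality: exogenous ancestor spikes arrive as a
#' Poisson process with rate `drive_rate`; every spike spawns
#' `Poisson(sigma)` child spikes on uniformly random units at the next time
#' step. At `sigma = 1` (branching parameter one) the total cascade sizes
#' follow the critical Galton-Watson (Borel) distribution with tail exponent
#' -3/2, the canonical avalanche-size power law. Cascades are laid out
#' serially with at least `guard` silent steps between them so that avalanche
#' extraction recovers them cleanly.
#'
#' @param n_units number of units.
#' @param sigma branching parameter (mean offspring per spike).
#' @param drive_rate rate of exogenous ancestors per time step; inter-cascade
#'   gaps are `guard + Exp(drive_rate)`.
#' @param duration approximate raster length in steps; generation stops at
#'   the first cascade ending beyond it. Alternatively give `n_cascades`.
#' @param n_cascades exact number of cascades to generate (overrides
#'   `duration`).
#' @param guard minimum silent gap between cascades (steps).
#' @param max_size scale of the cascade-size cutoff. Each cascade is
#'   truncated at a size drawn uniformly from `[max_size/5, max_size]`:
#'   critical and supercritical cascades have unbounded expected size, and a
#'   finite system cuts them off at a variable effective size (refractory
#'   depletion, boundary effects), which spreads the truncated mass over a
#'   range of sizes instead of piling it at one point.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return A [spike_raster()] with integer event times.
#' @examples
#' r <- branching_raster(10, sigma = 0.5, drive_rate = 0.05,
#'                       n_cascades = 100, seed = 1)
#' @export
branching_raster <- function(n_units, sigma, drive_rate = 0.005,
                             duration = NULL, n_cascades = NULL,
                             guard = 10, max_size = 2500, seed = NULL) {
  stopifnot(n_units >= 1, sigma >= 0, drive_rate > 0)
  if (is.null(duration) && is.null(n_cascades))
    stop("give either 'duration' or 'n_cascades'")
  if (!is.null(seed)) set.seed(seed)
  times <- vector("list", 1024L)
  units <- vector("list", 1024L)
  k <- 0L
  t_cursor <- 0
  repeat {
    if (!is.null(n_cascades) && k >= n_cascades) break
    if (is.null(n_cascades) && t_cursor > duration) break
    t_cursor <- t_cursor + guard + stats::rexp(1, drive_rate)
    onset <- round(t_cursor)
    # one Galton-Watson cascade, generation by generation
    cap <- ceiling(runif(1, max_size / 5, max_size))
    gen_sizes <- 1L
    total <- 1L
    current <- 1L
    while (current > 0L && total < cap) {
      nxt <- sum(rpois(current, sigma))
      nxt <- min(nxt, cap - total)
      gen_sizes <- c(gen_sizes, nxt)
      total <- total + nxt
      current <- nxt
    }
    gen_sizes <- gen_sizes[gen_sizes > 0L]
    tt <- rep(onset + seq_along(gen_sizes) - 1L, gen_sizes)
    uu <- sample.int(n_units, total, replace = TRUE)
    k <- k + 1L
    if (k > length(times)) {
      length(times) <- 2L * length(times)
      length(units) <- 2L * length(units)
    }
    times[[k]] <- tt
    units[[k]] <- uu
    t_cursor <- onset + length(gen_sizes) - 1L
  }
  tt <- unlist(times[seq_len(k)])
  uu <- unlist(units[seq_len(k)])
  spike_raster(tt, uu, n_units = n_units,
               duration = max(tt) + guard, time_unit = "steps", t_start = 0)
}
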