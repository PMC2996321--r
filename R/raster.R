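#' Spike raster objects
#'
#' The common currency of the package: a timestamped list of spike events
#' over a declared set of units. Model output and multi-electrode-array
#' recordings share this representation.
#'
#' @param time numeric vector of event times (sorted on construction).
#' @param unit integer vector of unit ids in `1..n_units`.
#' @param n_units number of declared units (defaults to `max(unit)`).
#' @param duration recording length in time units (defaults to the observed
#'   span).
#' @param time_unit label, e.g. `"steps"` or `"ms"`.
#' @param t_start start of the recording window.
#' @return An object of class `spike_raster`: a list with `events` (data
#'   frame with columns `time`, `unit`, sorted by time), `n_units`,
#'   `duration`, `time_unit`, `t_start`.
#' @export
spike_raster <- function(time, unit, n_units = NULL, duration = NULL,
                         time_unit = "steps", t_start = NULL) {
  stopifnot(length(time) == length(unit))
  unit <- as.integer(unit)
  if (length(unit) && min(unit) < 1L)
    stop("unit ids must be >= 1", call. = FALSE)
  if (is.null(n_units))
    n_units <- if (length(unit)) max(unit) else 1L
  if (length(unit) && max(unit) > n_units)
    stop("unit id exceeds n_units", call. = FALSE)
  o <- order(time, unit)
  time <- time[o]; unit <- unit[o]
  if (is.null(t_start)) t_start <- if (length(time)) min(time) else 0
  if (is.null(duration))
    duration <- if (length(time)) max(time) - t_start + 1 else 1
  r <- list(events = data.frame(time = time, unit = unit),
            n_units = as.integer(n_units),
            duration = duration, time_unit = time_unit, t_start = t_start)
  class(r) <- "spike_raster"
  r
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("spike_raster: %d events, %d units, duration %g %s\n",
              nrow(x$events), x$n_units, x$duration, x$time_unit))
  invisible(x)
}

#' @export
summary.spike_raster <- function(object, ...) {
  ev <- object$events
  cnt <- tabulate(ev$unit, nbins = object$n_units)
  cat(sprintf("spike_raster: %d events over %d units (%d active), %g %s\n",
              nrow(ev), object$n_units, sum(cnt > 0), object$duration,
              object$time_unit))
  cat(sprintf("  pooled rate %.4g events per %s; per-unit spike counts:\n",
              nrow(ev) / object$duration, sub("s$", "", object$time_unit)))
  print(summary(cnt))
  invisible(object)
}

#' Restrict a raster to a time window
#'
#' @param raster a [spike_raster()].
#' @param from,to window bounds; events with `from <= time < to` are kept.
#' @return A `spike_raster` covering the window.
#' @export
raster_window <- function(raster, from, to) {
  keep <- raster$events$time >= from & raster$events$time < to
  spike_raster(raster$events$time[keep], raster$events$unit[keep],
               n_units = raster$n_units, duration = to - from,
               time_unit = raster$time_unit, t_start = from)
}

#' Retain a subset of units
#'
#' @param raster a [spike_raster()].
#' @param units integer ids of the units to keep; they are renumbered
#'   consecutively.
#' @return A `spike_raster` over `length(units)` units.
#' @export
raster_subset <- function(raster, units) {
  units <- sort(unique(as.integer(units)))
  keep <- raster$events$unit %in% units
  remap <- match(raster$events$unit[keep], units)
  spike_raster(raster$events$time[keep], remap,
               n_units = length(units), duration = raster$duration,
               time_unit = raster$time_unit, t_start = raster$t_start)
}

#' Read a spike raster from a delimited event table
#'
#' Expects a tab-delimited file with a header line and two columns, time and
#' unit id. The `dialect` handles unit-id base and time units; events are
#' sorted on load.
#'
#' @param path file path.
#' @param unit_base 0 or 1: the id convention of the file. Ids are
#'   normalised to 1-based internally.
#' @param time_unit label stored on the raster, e.g. `"steps"` or `"ms"`.
#' @param n_units declared number of units; default: largest id seen.
#' @return A [spike_raster()].
#' @export
read_raster <- function(path, unit_base = 1L, time_unit = "steps",
                        n_units = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) <= 1L) {
    warning("no events in ", path)
    return(spike_raster(numeric(0), integer(0), n_units = n_units %||% 1L,
                        time_unit = time_unit))
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("malformed line %d in %s: expected 2 tab-separated fields",
                 bad[1] + 1L, path), call. = FALSE)
  m <- matrix(unlist(parts), ncol = 2, byrow = TRUE)
  time <- suppressWarnings(as.numeric(m[, 1]))
  unit <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(time) || anyNA(unit)) {
    bad <- which(is.na(time) | is.na(unit))[1]
    stop(sprintf("malformed line %d in %s: non-numeric field", bad + 1L, path),
         call. = FALSE)
  }
  spike_raster(time, unit + (1L - as.integer(unit_base)),
               n_units = n_units, time_unit = time_unit)
}

#' Write a spike raster to a tab-delimited event table
#'
#' Deterministic ordering (time, then unit), header line `time<TAB>unit`.
#' Round-trip safe with [read_raster()].
#'
#' @param raster a [spike_raster()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  ev <- raster$events[order(raster$events$time, raster$events$unit), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time\tunit", con)
  if (nrow(ev))
    writeLines(paste(sprintf("%.12g", ev$time), ev$unit, sep = "\t"), con)
  invisible(path)
}

#' Write a trajectory table
#'
#' Tab-delimited per-window means with a header, as produced by
#' [simulate_network()].
#'
#' @param traj trajectory data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(traj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
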