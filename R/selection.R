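#' Electrode selection for culture-like recordings
#'
#' Clustering of neurons on few electrodes distorts avalanche statistics, so
#' units whose spike count exceeds the across-unit mean by more than
#' `sd_mult` standard deviations are excluded (single pass: the mean and SD
#' are computed once over all declared units and not recomputed after
#' exclusion). A recording is accepted for criticality analysis only if at
#' least `min_active` retained units are active (have at least one spike).
#'
#' @param raster a [spike_raster()].
#' @param min_active minimum number of active retained units (default 50).
#' @param sd_mult exclusion threshold in standard deviations (default 2);
#'   exclusion requires a count strictly greater than the threshold, so a
#'   degenerate recording with identical counts (SD 0) keeps every unit.
#' @return A list with `raster` (the filtered raster, units renumbered) and
#'   `report`, an object of class `selection_report` holding per-unit counts,
#'   the excluded units with reasons, `n_active` and the `accepted` flag.
#' @export
electrode_selection <- function(raster, min_active = 50L, sd_mult = 2) {
  if (nrow(raster$events) == 0L) stop("empty raster", call. = FALSE)
  counts <- tabulate(raster$events$unit, nbins = raster$n_units)
  thr <- mean(counts) + sd_mult * stats::sd(counts)
  excluded <- which(counts > thr)
  retained <- setdiff(seq_len(raster$n_units), excluded)
  out <- raster_subset(raster, retained)
  n_active <- sum(counts[retained] > 0L)
  report <- list(counts = counts,
                 excluded_units = excluded,
                 reason = if (length(excluded))
                   sprintf("count %d > mean + %g SD (%.2f)",
                           counts[excluded], sd_mult, thr)
                 else character(0),
                 threshold = thr,
                 retained_units = retained,
                 n_active = n_active,
                 min_active = as.integer(min_active),
                 accepted = n_active >= min_active)
  class(report) <- "selection_report"
  list(raster = out, report = report)
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("electrode selection: %d/%d units retained, %d active; %s\n",
              length(x$retained_units), length(x$counts), x$n_active,
              if (x$accepted) "ACCEPTED" else
                sprintf("REJECTED (need >= %d active)", x$min_active)))
  if (length(x$excluded_units))
    cat("  excluded:", paste(x$excluded_units, collapse = ", "),
        sprintf("(count > %.2f)\n", x$threshold))
  invisible(x)
}
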