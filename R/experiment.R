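#' Full developmental experiment with staged inhibition
#'
#' Reproduces the canonical in-silico protocol: the network develops from an
#' unconnected state; at the calcium crossing 20% of the neurons switch to
#' inhibitory with a strong onset weight; after the post-transition epoch the
#' inhibitory strength is gradually reduced to its final (balanced) value and
#' the network re-equilibrates. Avalanche analyses are run in four windows -
#' early development (initial state), the activity overshoot just after the
#' switch, the strongly inhibited homeostatic epoch, and the re-balanced
#' epoch - mirroring the initial / supercritical / subcritical / critical
#' progression of developing cultures.
#'
#' @param params a [model_params()] object (homeostatic regime recommended).
#' @param seed integer seed for the whole experiment.
#' @param w_inh_onset inhibitory weight magnitude at the switch (default
#'   `10 * w_exc`, the strong-onset scenario).
#' @param w_inh_final inhibitory weight after the gradual reduction (default
#'   `w_exc`, balanced inhibition).
#' @param phase_a_steps length of the first segment (development + strongly
#'   inhibited epoch).
#' @param ramp_increments,ramp_step_len the reduction is applied in
#'   `ramp_increments` equal weight steps of `ramp_step_len` steps each.
#' @param equil_steps length of the final (balanced) segment.
#' @param equil_skip steps discarded at the start of the final segment before
#'   the critical-state window.
#' @param run_tests also run the criticality test battery (subsampling, bin
#'   robustness, scaling collapse, Fano) on the final window.
#' @param ... analysis options passed to [avalanche_analysis()].
#' @return An object of class `phase_experiment`: `windows` (named list of
#'   [avalanche_analysis()] fits), `summary` (data frame with window, span,
#'   number of avalanches, exponent, deviation, label), `switched_at`,
#'   `trajectory` (all segments row-bound), `phases` (labels from
#'   [detect_phase()] on the first segment), `inhib_share` (percent of total
#'   synaptic density with inhibitory presynapse at the end), `tests`
#'   (optional battery), `state`, `params`, `seed`.
#' @export
run_phase_experiment <- function(params = model_params(), seed = 1L,
                                 w_inh_onset = 10 * params$w_exc,
                                 w_inh_final = params$w_exc,
                                 phase_a_steps = 80000L,
                                 ramp_increments = 10L,
                                 ramp_step_len = 2000L,
                                 equil_steps = 60000L,
                                 equil_skip = 20000L,
                                 run_tests = FALSE, ...) {
  pA <- params
  pA$w_inh <- w_inh_onset
  A <- simulate_network(pA, phase_a_steps, switch = "ca-crossing", seed = seed)
  sw <- A$switched_at
  if (is.na(sw))
    stop("the network did not reach the calcium target within phase_a_steps",
         call. = FALSE)

  state <- A$state
  trajs <- list(A$trajectory)
  w_seq <- seq(w_inh_onset, w_inh_final, length.out = ramp_increments)
  for (wv in w_seq) {
    state <- apply_inhibition_jump(state, wv)
    pB <- params; pB$w_inh <- wv
    B <- simulate_network(pB, ramp_step_len, init_state = state,
                          switch = "none", record_raster = FALSE)
    state <- B$state
    trajs <- c(trajs, list(B$trajectory))
  }
  pC <- params; pC$w_inh <- w_inh_final
  C <- simulate_network(pC, equil_steps, init_state = state, switch = "none")
  trajs <- c(trajs, list(C$trajectory))
  c_start <- C$trajectory$t[1] - 1

  win <- list(
    initial = raster_window(A$raster, 0, floor(0.85 * sw)),
    # the activity overshoot brackets the calcium crossing: Phase II starts
    # at the activity maximum, slightly before the conversion fires
    overshoot = raster_window(A$raster, sw - 2000, sw + 4000),
    strong_inhibition = raster_window(A$raster,
                                      max(sw + 10000, phase_a_steps - 30000),
                                      phase_a_steps),
    balanced_inhibition = raster_window(C$raster, c_start + equil_skip,
                                        c_start + equil_steps))
  fits <- lapply(win, function(r)
    tryCatch(avalanche_analysis(r, ...), error = function(e) {
      out <- list(time_bin = NA_real_, n_avalanches = NA_integer_,
                  exponent = NA_real_, delta = NA_real_,
                  label = NA_character_, note = conditionMessage(e))
      class(out) <- "avalanche_fit"
      out
    }))
  summary <- data.frame(
    window = names(win),
    n_spikes = vapply(win, function(r) nrow(r$events), numeric(1)),
    time_bin = vapply(fits, `[[`, numeric(1), "time_bin"),
    n_avalanches = vapply(fits, function(f) as.numeric(f$n_avalanches),
                          numeric(1)),
    exponent = vapply(fits, `[[`, numeric(1), "exponent"),
    delta = vapply(fits, `[[`, numeric(1), "delta"),
    label = vapply(fits, `[[`, character(1), "label"),
    row.names = NULL)

  omega <- C$state$omega
  inhib_cols <- C$state$inhib_idx
  inhib_share <- if (length(inhib_cols) && sum(omega) > 0)
    100 * sum(omega[, inhib_cols]) / sum(omega) else 0

  tests <- NULL
  if (run_tests) {
    wb <- win$balanced_inhibition
    tests <- list(
      subsample = spatial_subsample_test(wb, c(1, 0.75, 0.5), seed = seed),
      bins = bin_robustness_test(wb),
      collapse = tryCatch(scaling_function_collapse(wb),
                          error = function(e) conditionMessage(e)),
      fano = fano_factor(wb))
  }

  out <- list(windows = fits, rasters = win, summary = summary,
              switched_at = sw,
              trajectory = do.call(rbind, trajs),
              phases = detect_phase(A$trajectory, params),
              inhib_share = inhib_share,
              tests = tests, state = C$state, params = params, seed = seed)
  class(out) <- "phase_experiment"
  out
}

#' @export
print.phase_experiment <- function(x, ...) {
  cat(sprintf("phase experiment (seed %d): inhibitory conversion at step %d\n",
              x$seed, x$switched_at))
  print(transform(x$summary,
                  exponent = round(exponent, 2),
                  time_bin = signif(time_bin, 3),
                  delta = round(delta, 3)))
  cat(sprintf("final inhibitory share of synaptic density: %.1f%%\n",
              x$inhib_share))
  invisible(x)
}

#' @export
plot.phase_experiment <- function(x, ...) {
  tr <- x$trajectory
  op <- graphics::par(mfrow = c(3, 1), mar = c(3.5, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(tr$t, tr$ca_bar, type = "l", xlab = "", ylab = "mean calcium")
  graphics::abline(h = x$params$ca_target, lty = 3)
  graphics::abline(v = x$switched_at, lty = 2)
  graphics::plot(tr$t, tr$a_bar, type = "l", ylim = range(c(tr$a_bar, tr$d_bar)),
                 xlab = "", ylab = "field radii")
  graphics::lines(tr$t, tr$d_bar, lty = 2)
  graphics::legend("topright", lty = 1:2, legend = c("axonal", "dendritic"),
                   bty = "n")
  graphics::plot(tr$t, tr$rate, type = "l", xlab = "time step",
                 ylab = "rate /neuron/step")
  invisible(x)
}

#' Acute inhibition change in an equilibrated network
#'
#' Equilibrates a balanced network, then suddenly sets the inhibitory weight
#' to `new_w_inh` and follows the response: the avalanche statistics change
#' immediately (towards supercritical for a decrease, subcritical for an
#' increase), the firing rate relaxes back to the homeostatic value, and the
#' connectivity settles at a lastingly different level.
#'
#' @param params a [model_params()] object.
#' @param new_w_inh inhibitory weight magnitude after the jump.
#' @param seed integer seed.
#' @param pre_steps equilibration length before the jump.
#' @param post_window length of the immediately-after analysis window.
#' @param recovery_steps additional steps after the jump.
#' @param ... passed to [avalanche_analysis()].
#' @return An object of class `inhibition_jump`: fits `pre`, `post`,
#'   `late`; rates and mean densities before/after; the jump step.
#' @export
run_inhibition_jump <- function(params = model_params(), new_w_inh,
                                seed = 1L, pre_steps = 110000L,
                                post_window = 25000L,
                                recovery_steps = 60000L, ...) {
  A <- simulate_network(params, pre_steps, switch = "ca-crossing", seed = seed)
  if (is.na(A$switched_at))
    stop("network did not switch within pre_steps", call. = FALSE)
  state <- apply_inhibition_jump(A$state, new_w_inh)
  p2 <- params; p2$w_inh <- new_w_inh
  B <- simulate_network(p2, recovery_steps, init_state = state, switch = "none")
  t_jump <- pre_steps
  pre_win <- raster_window(A$raster, pre_steps - 30000, pre_steps)
  post_win <- raster_window(B$raster, t_jump, t_jump + post_window)
  late_win <- raster_window(B$raster, t_jump + recovery_steps - 25000,
                            t_jump + recovery_steps)
  fits <- lapply(list(pre = pre_win, post = post_win, late = late_win),
                 function(r) tryCatch(avalanche_analysis(r, ...),
                                      error = function(e) NULL))
  trA <- A$trajectory; trB <- B$trajectory
  nA <- nrow(trA); nB <- nrow(trB)
  tail_idx <- function(n) seq(max(1, n - max(1, n %/% 5)), n)
  out <- list(
    pre = fits$pre, post = fits$post, late = fits$late,
    t_jump = t_jump,
    rate_pre = mean(trA$rate[tail_idx(nA)]),
    rate_late = mean(trB$rate[tail_idx(nB)]),
    omega_pre = mean(trA$omega_bar[tail_idx(nA)]),
    omega_late = mean(trB$omega_bar[tail_idx(nB)]),
    trajectory = rbind(trA, trB),
    params = params, new_w_inh = new_w_inh, seed = seed)
  class(out) <- "inhibition_jump"
  out
}

#' @export
print.inhibition_jump <- function(x, ...) {
  dir <- if (x$new_w_inh < x$params$w_inh) "decrease" else "increase"
  cat(sprintf("inhibition jump (%s: %g -> %g) at step %d\n",
              dir, x$params$w_inh, x$new_w_inh, x$t_jump))
  dd <- function(f) if (is.null(f) || is.na(f$delta)) "NA" else
    sprintf("%+.3f (%s)", f$delta, f$label)
  cat(sprintf("  deviation: pre %s -> post %s -> late %s\n",
              dd(x$pre), dd(x$post), dd(x$late)))
  cat(sprintf("  rate: %.4g -> %.4g; mean density: %.4g -> %.4g\n",
              x$rate_pre, x$rate_late, x$omega_pre, x$omega_late))
  invisible(x)
}

#' Plateau of the mean membrane potential during the activity overshoot
#'
#' Runs an excitatory-only network (no inhibitory conversion) through the
#' phase transition and measures the plateau of the population-averaged
#' membrane potential: the maximum of its running mean over `smooth` steps.
#' In the explosive-transition regime the plateau sits at the hard bound
#' (mean potential ~ 1) because connectivity overshoots far beyond the
#' sustained-activity threshold before calcium catches up.
#'
#' @param params a [model_params()] object; the explosive regime is the
#'   intended setting.
#' @param n_steps run length; must cover the transition (default 25000).
#' @param seed integer seed.
#' @param smooth width (steps) of the plateau-defining running mean.
#' @return The plateau value (scalar in `[0, 1]`), with the full trajectory
#'   as attribute `"trajectory"`.
#' @export
overshoot_plateau <- function(params = model_params(regime = "explosive"),
                              n_steps = 25000L, seed = 1L, smooth = 200L) {
  p <- params
  p$inhib_fraction <- 0
  sim <- simulate_network(p, n_steps, switch = "none", seed = seed,
                          record_every = 10L, record_raster = FALSE)
  v <- sim$trajectory$v_bar
  wp <- max(1L, as.integer(round(smooth / 10L)))
  rm <- stats::filter(v, rep(1 / wp, wp), sides = 2)
  out <- max(rm, na.rm = TRUE)
  attr(out, "trajectory") <- sim$trajectory
  out
}
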