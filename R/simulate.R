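#' Simulate the developing network
#'
#' Runs the growth network for `n_steps` Euler steps (dynamics and growth
#' both applied every step), optionally firing the one-time inhibitory
#' conversion, and records the spike raster together with population-mean
#' trajectories. Runs are fully reproducible from the seed: the compiled
#' engine draws from R's RNG stream, and `engine = "r"` (a pure-R reference
#' built from [step_dynamics()] and [update_growth()]) produces bit-identical
#' output.
#'
#' @param params a [model_params()] object.
#' @param n_steps number of time steps to simulate.
#' @param init_state optional `network_state` to continue from; when `NULL` a
#'   fresh state is created with [init_network()].
#' @param switch when to convert the inhibitory subset: `"ca-crossing"`
#'   (default; the first step at which mean calcium reaches the target),
#'   `"step"` (at `switch_step`), or `"none"`. Ignored if the state has
#'   already switched.
#' @param switch_step absolute step for `switch = "step"`.
#' @param record_every cadence (steps) of the trajectory recording.
#' @param record_raster logical; collect the spike raster?
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference).
#' @param seed integer seed applied before the run, or `NULL` to continue the
#'   current RNG stream (useful for segmented runs). Defaults to
#'   `params$seed` for fresh runs and `NULL` when continuing from
#'   `init_state`.
#'
#' @return An object of class `sim_result` with elements `raster` (a
#'   [spike_raster()]), `trajectory` (data frame of per-window means: `t`,
#'   `v_bar`, `ca_bar`, `a_bar`, `d_bar`, `omega_bar`, `rate`), `state` (the
#'   final `network_state`), `switched_at` (step of the inhibitory
#'   conversion, or `NA`), and `params`.
#' @examples
#' p <- model_params(n_neurons = 25, grid_rows = 5, grid_cols = 5, seed = 7)
#' sim <- simulate_network(p, 2000, record_every = 20)
#' head(sim$trajectory)
#' @export
simulate_network <- function(params, n_steps,
                             init_state = NULL,
                             switch = c("ca-crossing", "step", "none"),
                             switch_step = NULL,
                             record_every = 50L,
                             record_raster = TRUE,
                             engine = c("cpp", "r"),
                             seed = if (is.null(init_state)) params$seed else NULL) {
  switch_ <- match.arg(switch)
  engine <- match.arg(engine)
  validate_model_params(params)
  stopifnot(n_steps >= 1L, record_every >= 1L)
  if (!is.null(seed)) set.seed(seed)
  state <- if (is.null(init_state)) init_network(params) else init_state
  switch_mode <- switch(switch_, "none" = 0L, "ca-crossing" = 1L, "step" = 2L)
  if (switch_mode == 2L && is.null(switch_step))
    stop("switch = \"step\" requires 'switch_step'", call. = FALSE)

  if (engine == "cpp") {
    dist <- as.matrix(stats::dist(state$positions))
    r <- .sim_core_cpp(as.integer(n_steps),
                       state$v, state$ca, state$a, state$d,
                       state$eps, as.integer(state$refrac), dist,
                       params$tau_v, params$tau_ca, params$v_rest,
                       params$beta_ca, params$ca_target,
                       params$rho_d, params$rho_a,
                       params$refractory_steps, params$v_floor,
                       if (params$kernel == "disk") 0L else 1L,
                       as.integer(state$inhib_idx), params$w_inh,
                       switch_mode,
                       as.integer(switch_step %||% 0L),
                       state$gaba_switched,
                       as.integer(record_every), record_raster,
                       as.integer(state$t))
    out_state <- state
    out_state$v <- r$v; out_state$ca <- r$ca
    out_state$a <- r$a; out_state$d <- r$d
    out_state$eps <- r$eps; out_state$refrac <- r$refrac
    out_state$omega <- r$omega
    out_state$t <- state$t + as.integer(n_steps)
    out_state$gaba_switched <- r$gaba_switched
    traj <- as.data.frame(r$traj)
    names(traj) <- c("t", "v_bar", "ca_bar", "a_bar", "d_bar", "omega_bar", "rate")
    sp_t <- r$spike_t; sp_u <- r$spike_u
    switched_at <- if (r$switched_at >= 0) r$switched_at else NA_integer_
  } else {
    n <- params$n_neurons
    sp_t <- integer(0); sp_u <- integer(0)
    nrec <- n_steps %/% record_every
    traj <- matrix(NA_real_, nrec, 7)
    rec_i <- 0L; win_spikes <- 0L
    switched_at <- NA_integer_
    sp_tl <- vector("list", n_steps); sp_n <- 0L
    for (step in seq_len(n_steps)) {
      t_now <- state$t  # step index being simulated
      upd <- step_dynamics(state, params)
      state <- upd$state
      if (record_raster && length(upd$spikes)) {
        sp_n <- sp_n + 1L
        sp_tl[[sp_n]] <- cbind(t_now, upd$spikes)
      }
      win_spikes <- win_spikes + length(upd$spikes)
      state <- update_growth(state, params)
      if (!state$gaba_switched && switch_mode != 0L) {
        trig <- if (switch_mode == 1L) mean(state$ca) >= params$ca_target
                else t_now >= switch_step
        if (trig) {
          state$eps[state$inhib_idx] <- -params$w_inh
          state$gaba_switched <- TRUE
          switched_at <- t_now
        }
      }
      if (step %% record_every == 0L && rec_i < nrec) {
        rec_i <- rec_i + 1L
        nn <- length(state$v)
        traj[rec_i, ] <- c(t_now, mean(state$v), mean(state$ca),
                           mean(state$a), mean(state$d),
                           sum(state$omega) / (nn * (nn - 1)),
                           win_spikes / (nn * record_every))
        win_spikes <- 0L
      }
    }
    if (sp_n > 0L) {
      m <- do.call(rbind, sp_tl[seq_len(sp_n)])
      sp_t <- as.integer(m[, 1]); sp_u <- as.integer(m[, 2])
    }
    traj <- as.data.frame(traj)
    names(traj) <- c("t", "v_bar", "ca_bar", "a_bar", "d_bar", "omega_bar", "rate")
    out_state <- state
  }

  raster <- if (record_raster)
    spike_raster(sp_t, sp_u, n_units = params$n_neurons,
                 duration = n_steps, time_unit = "steps",
                 t_start = out_state$t - n_steps)
  else NULL
  res <- list(raster = raster, trajectory = traj, state = out_state,
              switched_at = switched_at, params = params)
  class(res) <- "sim_result"
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sim_result <- function(x, ...) {
  tr <- x$trajectory
  n <- nrow(tr)
  cat(sprintf("sim_result: %d steps, %s spikes recorded\n",
              x$state$t - (tr$t[1] %||% 0),
              if (is.null(x$raster)) "no" else format(nrow(x$raster$events))))
  if (!is.na(x$switched_at))
    cat(sprintf("  inhibitory conversion at step %d\n", x$switched_at))
  if (n) {
    ti <- seq(max(1, n - max(1, n %/% 10)), n)
    cat(sprintf("  final means: V = %.4g, Ca = %.4g, Omega = %.4g, rate = %.4g\n",
                mean(tr$v_bar[ti]), mean(tr$ca_bar[ti]),
                mean(tr$omega_bar[ti]), mean(tr$rate[ti])))
  }
  invisible(x)
}

#' Label the developmental phases of a trajectory
#'
#' Phase I lasts while mean calcium is below the homeostatic target (dendritic
#' outgrowth); Phase II starts at the first crossing of the target (activity
#' overshoot, dendritic pruning, axonal growth); Phase III starts once the
#' smoothed mean calcium stays within `tol` of the target over a sliding
#' window of `window` steps (morphological homeostasis). Labels are
#' contiguous and ordered I, II, III; trajectories that never reach a later
#' phase simply carry the labels attained so far.
#'
#' @param traj trajectory data frame from [simulate_network()].
#' @param params the [model_params()] of the run.
#' @param tol relative calcium tolerance defining homeostasis.
#' @param window width (steps) of the smoothing / persistence window. The
#'   default matches the slow post-transition relaxation of the homeostatic
#'   regime; single-window calcium fluctuations in the bursty steady state
#'   are of order 10-30% on shorter scales.
#' @return Character vector (`"I"`, `"II"`, `"III"`) with one label per
#'   trajectory row.
#' @export
detect_phase <- function(traj, params, tol = 0.1, window = 20000) {
  stopifnot(nrow(traj) > 0)
  ca <- traj$ca_bar
  n <- length(ca)
  target <- params$ca_target
  rec_dt <- if (n > 1) stats::median(diff(traj$t)) else 1
  wp <- max(1L, min(n, as.integer(round(window / rec_dt))))
  # centred running mean with truncated windows at the edges
  h <- wp %/% 2L
  cs0 <- c(0, cumsum(ca))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  sm <- (cs0[hi + 1L] - cs0[lo]) / (hi - lo + 1L)
  cross <- which(ca >= target)[1]
  lab <- rep("I", n)
  if (is.na(cross)) return(lab)
  lab[cross:n] <- "II"
  ok <- abs(sm - target) / target <= tol
  # first index >= cross from which ok holds for a full window ahead
  run_ok <- rev(cumsum(rev(!ok)))  # number of violations at or after i
  viol_after <- function(i) run_ok[i] - (if (i + wp <= n) run_ok[i + wp] else 0)
  i3 <- NA_integer_
  for (i in cross:n) {
    if (viol_after(i) == 0) { i3 <- i; break }
  }
  if (!is.na(i3)) lab[i3:n] <- "III"
  lab
}
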