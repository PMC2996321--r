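#' Initialise a network state
#'
#' All neurons start excitatory with the membrane potential at rest, calcium
#' at the steady-state value implied by spontaneous firing at `v_rest`
#' (`beta_ca * v_rest * tau_ca`), and field radii `a_init`, `d_init` chosen
#' so that no connections exist. The inhibitory candidate subset (converted
#' later by [apply_gaba_switch()]) is sampled here, uniformly without
#' replacement, so that runs are reproducible from the seed in force.
#'
#' @param params a [model_params()] object.
#' @return An object of class `network_state`: per-neuron vectors `v`, `ca`,
#'   `a`, `d`, `eps`, `refrac`, the position matrix, the connectivity matrix
#'   `omega`, the step counter `t`, the sampled `inhib_idx` and the
#'   `gaba_switched` flag.
#' @export
init_network <- function(params) {
  validate_model_params(params)
  n <- params$n_neurons
  positions <- grid_positions(params)
  n_inhib <- floor(params$inhib_fraction * n)
  inhib_idx <- if (n_inhib > 0) sort(sample.int(n, n_inhib)) else integer(0)
  st <- list(
    v = rep(params$v_rest, n),
    ca = rep(params$beta_ca * params$v_rest * params$tau_ca, n),
    a = rep(params$a_init, n),
    d = rep(params$d_init, n),
    eps = rep(params$w_exc, n),
    refrac = integer(n),
    positions = positions,
    omega = compute_connectivity(rep(params$a_init, n), rep(params$d_init, n),
                                 positions, params$kernel),
    t = 0L,
    inhib_idx = inhib_idx,
    gaba_switched = FALSE)
  class(st) <- "network_state"
  st
}

#' @export
print.network_state <- function(x, ...) {
  n <- length(x$v)
  cat(sprintf("network_state: %d neurons at t = %d%s\n", n, x$t,
              if (x$gaba_switched) " (inhibition on)" else ""))
  cat(sprintf("  V = %.4g, Ca = %.4g, A = %.3g, D = %.3g, Omega = %.4g\n",
              mean(x$v), mean(x$ca), mean(x$a), mean(x$d),
              sum(x$omega) / (n * (n - 1))))
  invisible(x)
}

#' Advance the network dynamics by one time step
#'
#' Pure-R reference implementation of one Euler step: threshold firing with a
#' fresh uniform deviate per neuron, exponential relaxation of the potential
#' towards `v_rest` plus recurrent input from this step's spikes, calcium
#' decay plus per-spike influx, and refractory bookkeeping. A neuron that
#' spikes is eligible again on the `refractory_steps + 1`-th step after its
#' spike. Growth is applied separately by [update_growth()].
#'
#' The compiled engine used by [simulate_network()] performs the identical
#' update on the same RNG stream; the two produce bit-identical runs.
#'
#' @param state a `network_state`.
#' @param params a [model_params()] object.
#' @return `list(state = <updated state>, spikes = <integer vector of
#'   spiking neuron ids>)`.
#' @export
step_dynamics <- function(state, params) {
  n <- length(state$v)
  xi <- runif(n)
  spk <- state$refrac == 0L & state$v >= xi
  inp <- as.vector(state$omega %*% (state$eps * spk))
  v <- state$v + (params$v_rest - state$v) / params$tau_v + inp
  state$v <- pmin(1, pmax(params$v_floor, v))
  state$ca <- state$ca - state$ca / params$tau_ca + params$beta_ca * spk
  state$refrac <- ifelse(spk, params$refractory_steps,
                         pmax(0L, state$refrac - 1L))
  state$t <- state$t + 1L
  list(state = state, spikes = which(spk))
}

#' Apply one growth update to the axonal and dendritic fields
#'
#' The dendritic acceptance shrinks proportionally to the calcium excess over
#' the homeostatic target (and grows when calcium is below it); the axonal
#' supply behaves with inverted sign and its own rate. Radii are clipped at
#' zero and the connectivity matrix is recomputed from the new fields.
#'
#' @inheritParams step_dynamics
#' @return The updated `network_state`.
#' @export
update_growth <- function(state, params) {
  dev <- state$ca - params$ca_target
  state$d <- pmax(0, state$d - params$rho_d * dev)
  state$a <- pmax(0, state$a + params$rho_a * dev)
  state$omega <- compute_connectivity(state$a, state$d, state$positions,
                                      params$kernel)
  state
}

#' Convert the sampled subset of neurons to inhibitory
#'
#' Models the developmental switch of GABA action from excitatory to
#' inhibitory as a one-time sign flip of the coupling prefactor for the
#' subset sampled at initialisation (`floor(inhib_fraction * n)` neurons).
#'
#' @inheritParams step_dynamics
#' @return The updated `network_state` with `gaba_switched = TRUE`.
#' @export
apply_gaba_switch <- function(state, params) {
  if (state$gaba_switched)
    stop("the inhibitory conversion has already been applied", call. = FALSE)
  state$eps[state$inhib_idx] <- -params$w_inh
  state$gaba_switched <- TRUE
  state
}

#' Change the inhibitory strength of an equilibrated network
#'
#' Sets the coupling prefactor of all inhibitory neurons to `-new_w_inh`
#' instantly, as in acute pharmacological manipulation of inhibition.
#'
#' @param state a `network_state` with `gaba_switched = TRUE`.
#' @param new_w_inh non-negative new magnitude of the inhibitory coupling.
#' @return The updated `network_state`.
#' @export
apply_inhibition_jump <- function(state, new_w_inh) {
  if (!state$gaba_switched)
    stop("inhibition jump requires a network after the inhibitory conversion",
         call. = FALSE)
  if (!is.numeric(new_w_inh) || length(new_w_inh) != 1L || new_w_inh < 0)
    stop("'new_w_inh' must be a non-negative scalar", call. = FALSE)
  state$eps[state$inhib_idx] <- -new_w_inh
  state
}
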