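#' Model parameters for the neurite-outgrowth network
#'
#' Constructs and validates the parameter set of the growth-network
#' simulator. Neurons sit on a regular grid; each carries a membrane
#' potential `v`, a calcium concentration `ca`, a dendritic acceptance field
#' of radius `d` and an axonal supply field of radius `a`. Connectivity
#' `Omega[i, j]` is the geometric overlap of the dendritic zone of `i` with
#' the axonal zone of `j`, an abstract stand-in for the probability of
#' synapse formation. Growth follows the calcium deviation from the
#' homeostatic target: `d` shrinks and `a` grows when calcium is above
#' target, and vice versa.
#'
#' Two calibrated regimes are provided. The default, `"homeostatic"`,
#' develops through the three phases and settles into stable firing-rate
#' homeostasis with analysable avalanche statistics; it is the regime used by
#' [run_phase_experiment()]. The `"explosive"` regime slows the calcium
#' kinetics relative to growth (`tau_ca = 1e4`, `beta_ca = 0.05`) so that
#' field growth overshoots massively during the phase transition; it
#' reproduces the saturation of the mean membrane potential at its hard
#' bound of 1 during the activity overshoot of an excitatory-only network.
#' The steady-state firing rate implied by the calcium balance is
#' `ca_target / (beta_ca * tau_ca)` spikes per neuron per step in both
#' regimes (see [steady_state_rate()]).
#'
#' @param n_neurons number of neurons (default 100).
#' @param grid_rows,grid_cols grid dimensions; `grid_rows * grid_cols` must
#'   be at least `n_neurons`.
#' @param grid_spacing distance between neighbouring grid nodes.
#' @param tau_v membrane time constant (steps).
#' @param tau_ca calcium time constant (steps).
#' @param v_rest resting membrane potential, in `[0, 1)`. Doubles as the
#'   spontaneous per-step firing probability of an unconnected neuron.
#' @param beta_ca calcium influx per spike.
#' @param ca_target homeostatic calcium value.
#' @param rho_d,rho_a dendritic and axonal growth rates (radius units per
#'   step per unit calcium deviation).
#' @param w_exc excitatory coupling prefactor.
#' @param w_inh magnitude of the inhibitory coupling prefactor.
#' @param inhib_fraction fraction of neurons converted to inhibitory at the
#'   developmental switch, in `[0, 1]`.
#' @param refractory_steps refractory period after a spike (steps).
#' @param v_floor lower clip of the membrane potential.
#' @param a_init,d_init initial axonal / dendritic field radii; the defaults
#'   satisfy `a_init + d_init < grid_spacing` so that no connections exist
#'   initially. The explosive regime starts with a larger axonal reserve
#'   (8 instead of 5) so that an occasional premature half-ignition does not
#'   deplete the axons before the full transition completes.
#' @param kernel connectivity kernel, `"disk"` (intersection area of two
#'   circles, the default) or `"gaussian"` (overlap integral of two
#'   unnormalised Gaussian zones).
#' @param seed integer seed used by [simulate_network()] when no explicit
#'   seed is given.
#' @param regime `"homeostatic"` (default) or `"explosive"`; selects the
#'   calibrated defaults described above. Explicit arguments override the
#'   regime defaults.
#' @param ... ignored; present so that configuration lists can be spliced.
#'
#' @return An object of class `model_params` (a validated named list).
#' @examples
#' p <- model_params()
#' p$ca_target / (p$beta_ca * p$tau_ca)  # steady-state rate, 0.004
#' @seealso [simulate_network()], [init_network()], [steady_state_rate()]
#' @export
model_params <- function(n_neurons = 100L,
                         grid_rows = 10L, grid_cols = 10L,
                         grid_spacing = 10,
                         tau_v = 5, tau_ca = NULL,
                         v_rest = NULL, beta_ca = NULL, ca_target = NULL,
                         rho_d = NULL, rho_a = NULL,
                         w_exc = 0.02, w_inh = 0.02,
                         inhib_fraction = 0.2,
                         refractory_steps = 4L,
                         v_floor = 0,
                         a_init = NULL, d_init = 1,
                         kernel = c("disk", "gaussian"),
                         seed = 1L,
                         regime = c("homeostatic", "explosive"),
                         ...) {
  regime <- match.arg(regime)
  kernel <- match.arg(kernel)
  defaults <- switch(regime,
    homeostatic = list(tau_ca = 1000, v_rest = 2e-4, beta_ca = 0.5,
                       ca_target = 2, rho_d = 2e-4, rho_a = 4e-5,
                       a_init = 5),
    explosive   = list(tau_ca = 1e4, v_rest = 1e-4, beta_ca = 0.05,
                       ca_target = 5, rho_d = 4e-3, rho_a = 8e-4,
                       a_init = 8))
  if (is.null(tau_ca)) tau_ca <- defaults$tau_ca
  if (is.null(v_rest)) v_rest <- defaults$v_rest
  if (is.null(beta_ca)) beta_ca <- defaults$beta_ca
  if (is.null(ca_target)) ca_target <- defaults$ca_target
  if (is.null(rho_d)) rho_d <- defaults$rho_d
  if (is.null(rho_a)) rho_a <- defaults$rho_a
  if (is.null(a_init)) a_init <- defaults$a_init

  p <- list(n_neurons = as.integer(n_neurons),
            grid_rows = as.integer(grid_rows),
            grid_cols = as.integer(grid_cols),
            grid_spacing = grid_spacing,
            tau_v = tau_v, tau_ca = tau_ca,
            v_rest = v_rest, beta_ca = beta_ca, ca_target = ca_target,
            rho_d = rho_d, rho_a = rho_a,
            w_exc = w_exc, w_inh = w_inh,
            inhib_fraction = inhib_fraction,
            refractory_steps = as.integer(refractory_steps),
            v_floor = v_floor,
            a_init = a_init, d_init = d_init,
            kernel = kernel,
            seed = as.integer(seed),
            regime = regime,
            dt = 1)
  validate_model_params(p)
  class(p) <- "model_params"
  p
}

validate_model_params <- function(p) {
  stopifnot(p$n_neurons >= 1L)
  if (p$grid_rows * p$grid_cols < p$n_neurons)
    stop("grid capacity (grid_rows * grid_cols) is smaller than n_neurons",
         call. = FALSE)
  pos_fields <- c("grid_spacing", "tau_v", "tau_ca", "beta_ca", "ca_target",
                  "rho_d", "rho_a", "w_exc")
  for (f in pos_fields)
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || p[[f]] <= 0)
      stop(sprintf("'%s' must be a positive scalar", f), call. = FALSE)
  if (p$w_inh < 0) stop("'w_inh' must be non-negative", call. = FALSE)
  if (p$v_rest < 0 || p$v_rest >= 1)
    stop("'v_rest' must lie in [0, 1)", call. = FALSE)
  if (p$inhib_fraction < 0 || p$inhib_fraction > 1)
    stop("'inhib_fraction' must lie in [0, 1]", call. = FALSE)
  if (p$refractory_steps < 0L)
    stop("'refractory_steps' must be non-negative", call. = FALSE)
  if (p$a_init < 0 || p$d_init < 0)
    stop("initial field radii must be non-negative", call. = FALSE)
  if (p$dt != 1) stop("'dt' is fixed at one simulated time step", call. = FALSE)
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("Growth-network parameters (%s regime)\n", x$regime))
  cat(sprintf("  %d neurons on a %dx%d grid, spacing %g, kernel = %s\n",
              x$n_neurons, x$grid_rows, x$grid_cols, x$grid_spacing, x$kernel))
  cat(sprintf("  tau_v = %g, tau_ca = %g, v_rest = %g, v in [%g, 1]\n",
              x$tau_v, x$tau_ca, x$v_rest, x$v_floor))
  cat(sprintf("  beta_ca = %g, ca_target = %g  (steady-state rate %.4g /neuron/step)\n",
              x$beta_ca, x$ca_target, x$ca_target / (x$beta_ca * x$tau_ca)))
  cat(sprintf("  rho_d = %g, rho_a = %g, a0 = %g, d0 = %g\n",
              x$rho_d, x$rho_a, x$a_init, x$d_init))
  cat(sprintf("  w_exc = %g, w_inh = %g, inhibitory fraction = %g, refractory = %d\n",
              x$w_exc, x$w_inh, x$inhib_fraction, x$refractory_steps))
  invisible(x)
}

#' Read model parameters from a YAML configuration file
#'
#' The file holds a flat key-value mapping mirroring the arguments of
#' [model_params()]; unknown keys are rejected.
#'
#' @param path path to a YAML file.
#' @return A `model_params` object.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration file must be a key: value mapping")
  known <- names(formals(model_params))
  bad <- setdiff(names(cfg), setdiff(known, "..."))
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(model_params, cfg)
}
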