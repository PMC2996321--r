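# Mean-field companion to the simulator. Averaging the microscopic update
# over neurons replaces the recurrent spike sum by W * f(Omega_bar) * V_bar,
# where W is the mean coupling prefactor (w_exc for the purely excitatory
# analysis) and f the synaptic-density function, taken linear:
# f(Omega_bar) = n * Omega_bar (the mean row sum of the connectivity matrix).
# The dimensionless recurrent gain is g = tau_v * W * f(Omega_bar); g = 1
# separates bounded relaxation from the activity overshoot of the phase
# transition.

mf_gain <- function(params, omega_bar) {
  params$tau_v * params$w_exc * params$n_neurons * omega_bar
}

# expected firing rate of a neuron holding potential v under the uniform
# threshold rule with an absolute refractory period (renewal argument)
mf_rate <- function(v, refractory_steps) {
  v / (1 + refractory_steps * v)
}

#' Averaged dynamics at fixed connectivity
#'
#' Closed-form solution of the population-averaged potential and calcium
#' dynamics at a fixed mean synaptic density. Three regimes: zero coupling
#' (the potential relaxes to rest and calcium to a constant proportional to
#' it), sub-unity gain (bounded limits that exceed the zero-coupling case and
#' increase with density) and the transition regime `g >= 1`, in which the
#' potential saturates at its hard bound of 1 and calcium has no finite
#' limit (flagged divergent, never represented as a floating-point
#' overflow).
#'
#' @param params a [model_params()] object (the purely excitatory analysis
#'   uses `w_exc` as the effective coupling).
#' @param omega_bar mean pairwise synaptic density (scalar, >= 0).
#' @param v0,ca0 initial conditions of the averaged trajectories; default:
#'   rest.
#' @return An object of class `mean_field`: `regime` (`"zero"`,
#'   `"sub-unity"`, `"transition"`), `gain`, `V_limit`, `Ca_limit`,
#'   `ca_divergent`, `R_star` (firing rate at the potential limit), and
#'   callable trajectories `V_of_t(t)`, `Ca_of_t(t)`.
#' @export
mean_field_solution <- function(params, omega_bar, v0 = params$v_rest,
                                ca0 = NULL) {
  stopifnot(omega_bar >= 0)
  g <- mf_gain(params, omega_bar)
  tau_v <- params$tau_v; tau_ca <- params$tau_ca
  v_rest <- params$v_rest; beta <- params$beta_ca
  if (is.null(ca0)) ca0 <- beta * v_rest * tau_ca
  # exact solution of the discrete-time averaged map (Euler step length 1):
  #   v[t+1] = v[t] + (v_rest - v[t])/tau_v + g/tau_v * v[t]
  #   ca[t+1] = ca[t] - ca[t]/tau_ca + beta * v[t]
  # geometric bases lam (potential) and mu (calcium)
  lam <- 1 - (1 - g) / tau_v
  mu <- 1 - 1 / tau_ca
  if (g < 1) {
    regime <- if (omega_bar == 0) "zero" else "sub-unity"
    V_inf <- min(1, v_rest / (1 - g))
    Ca_inf <- beta * tau_ca * V_inf
    B <- beta * (v0 - V_inf) / (lam - mu)
    A <- ca0 - Ca_inf - B
    V_of_t <- function(t) V_inf + (v0 - V_inf) * lam^t
    Ca_of_t <- function(t) Ca_inf + A * mu^t + B * lam^t
    out <- list(regime = regime, gain = g, V_limit = V_inf,
                Ca_limit = Ca_inf, ca_divergent = FALSE,
                R_star = mf_rate(V_inf, params$refractory_steps),
                V_of_t = V_of_t, Ca_of_t = Ca_of_t)
  } else {
    # g >= 1: lam >= 1, the averaged potential grows until the hard bound
    V_rep <- v_rest / (1 - g)  # repelling formal fixed point (negative)
    t_hit <- if (lam > 1)
      ceiling(log((1 - V_rep) / (v0 - V_rep)) / log(lam)) else 0
    V_raw <- function(t) V_rep + (v0 - V_rep) * lam^t
    V_of_t <- function(t) pmin(1, V_raw(t))
    B <- beta * (v0 - V_rep) / (lam - mu)
    A0 <- ca0 - beta * tau_ca * V_rep - B
    ca_pre <- function(t) beta * tau_ca * V_rep + A0 * mu^t + B * lam^t
    ca_hit <- ca_pre(t_hit)
    lim <- beta * tau_ca  # ceiling forcing v = 1
    Ca_of_t <- function(t) {
      ifelse(t <= t_hit, ca_pre(t),
             lim + (ca_hit - lim) * mu^(t - t_hit))
    }
    out <- list(regime = "transition", gain = g, V_limit = 1,
                Ca_limit = Inf, ca_divergent = TRUE,
                R_star = mf_rate(1, params$refractory_steps),
                V_of_t = V_of_t, Ca_of_t = Ca_of_t)
  }
  class(out) <- "mean_field"
  out
}

#' @export
print.mean_field <- function(x, ...) {
  cat(sprintf("mean-field solution: %s regime (gain %.3g)\n", x$regime, x$gain))
  cat(sprintf("  V limit = %.4g, Ca limit = %s, rate at limit = %.4g\n",
              x$V_limit,
              if (x$ca_divergent) "divergent" else sprintf("%.4g", x$Ca_limit),
              x$R_star))
  invisible(x)
}

#' Steady-state firing rate from the calcium balance
#'
#' In homeostatic equilibrium the calcium concentration equals the target on
#' average, so the per-step balance `Ca/tau_ca = beta_ca * R` gives
#' `R* = ca_target / (beta_ca * tau_ca)` spikes per neuron per step, assuming
#' spikes uniformly distributed in time. `R*` grows with the calcium target
#' and falls with the calcium time constant and the per-spike influx.
#'
#' @param params a [model_params()] object (only `ca_target`, `beta_ca`,
#'   `tau_ca`, `refractory_steps` are used).
#' @return The rate `R*` (spikes/neuron/step) with attribute `feasible`;
#'   parameter sets implying a rate above the refractory ceiling
#'   `1/(refractory_steps + 1)` are flagged infeasible with a warning.
#' @examples
#' steady_state_rate(model_params(ca_target = 5, beta_ca = 0.5, tau_ca = 1000))
#' @export
steady_state_rate <- function(params) {
  r <- params$ca_target / (params$beta_ca * params$tau_ca)
  ceiling <- 1 / (params$refractory_steps + 1)
  feasible <- r <= ceiling
  if (!feasible)
    warning(sprintf("implied rate %.4g exceeds the refractory ceiling %.4g",
                    r, ceiling))
  attr(r, "feasible") <- feasible
  r
}

#' Nullcline of the averaged potential equation
#'
#' Stationary mean potential as a function of mean synaptic density, with a
#' sigmoid `1/(1 + exp(-k x))` replacing the Heaviside firing nonlinearity:
#' roots of `(v_rest - V)/tau_v + W f(Omega) sigmoid(k (V - v_theta)) = 0`.
#' For sufficiently steep `k` the solution set is S-shaped (a hysteresis
#' curve with up to three coexisting branches over an interval of
#' densities). Roots are located by a sign scan over a dense potential grid
#' followed by bracketed root refinement (tolerance 1e-10); grid points where
#' refinement fails are flagged, not fabricated.
#'
#' @param params a [model_params()] object.
#' @param omega_grid mean densities to scan (non-negative).
#' @param k sigmoid steepness.
#' @param v_theta sigmoid midpoint (effective threshold of the averaged
#'   firing nonlinearity).
#' @param n_scan size of the sign-scan grid over the potential.
#' @return A data frame (class `nullcline`) with columns `omega_bar`, `v`,
#'   `branch` (1 = lowest root at that density), `n_roots`, `converged`.
#' @export
nullcline <- function(params, omega_grid, k = 30, v_theta = 0.5,
                      n_scan = 2000) {
  stopifnot(all(omega_grid >= 0), k > 0)
  sig <- function(x) 1 / (1 + exp(-k * (x - v_theta)))
  vg <- seq(min(0, params$v_floor), 1, length.out = n_scan)
  rows <- vector("list", length(omega_grid))
  for (i in seq_along(omega_grid)) {
    om <- omega_grid[i]
    h <- function(V) (params$v_rest - V) / params$tau_v +
      params$w_exc * params$n_neurons * om * sig(V)
    hv <- h(vg)
    sgn <- sign(hv)
    cross <- which(sgn[-1] * sgn[-n_scan] < 0)
    roots <- numeric(0); conv <- logical(0)
    for (cidx in cross) {
      r <- tryCatch(stats::uniroot(h, c(vg[cidx], vg[cidx + 1]),
                                   tol = 1e-10),
                    error = function(e) NULL)
      if (is.null(r)) { roots <- c(roots, NA); conv <- c(conv, FALSE) }
      else { roots <- c(roots, r$root); conv <- c(conv, TRUE) }
    }
    exact <- which(hv == 0)
    if (length(exact)) { roots <- c(roots, vg[exact]); conv <- c(conv, TRUE) }
    # saturated branch: when the drive still exceeds the leak at the hard
    # bound, V = 1 is the (clipped) upper stationary state
    if (hv[n_scan] > 0) { roots <- c(roots, 1); conv <- c(conv, TRUE) }
    if (!length(roots)) next
    o <- order(roots)
    rows[[i]] <- data.frame(omega_bar = om, v = roots[o],
                            branch = seq_along(roots),
                            n_roots = length(roots), converged = conv[o])
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  class(out) <- c("nullcline", "data.frame")
  out
}

#' Homeostatic fixed point of the averaged system
#'
#' Intersects the stationary potential relation with the homeostasis
#' condition (firing rate equal to [steady_state_rate()]): the equilibrium
#' potential follows by inverting the threshold-firing rate relation
#' `r = V/(1 + refractory * V)`, and the equilibrium density from the
#' stationary potential equation. Because the equilibrium constrains only
#' the mean density, the fixed point corresponds in the (axonal, dendritic)
#' field plane to a whole set of points of approximately equal connectivity
#' (a hyperbola-like level curve); the returned predicate tests whether a
#' given field pair lies on it.
#'
#' @param params a [model_params()] object.
#' @param tol relative tolerance of the hyperbola predicate.
#' @return An object of class `mf_fixed_point`: `feasible`, `r_star`,
#'   `v_star`, `omega_star`, and `on_hyperbola(a_bar, d_bar)`, a predicate
#'   testing whether uniform fields of those radii yield a mean connectivity
#'   within `tol` of `omega_star`.
#' @export
fixed_point <- function(params, tol = 0.1) {
  r_star <- suppressWarnings(steady_state_rate(params))
  if (!attr(r_star, "feasible")) {
    out <- list(feasible = FALSE, r_star = as.numeric(r_star),
                v_star = NA_real_, omega_star = NA_real_,
                on_hyperbola = function(a_bar, d_bar) NA)
    class(out) <- "mf_fixed_point"
    return(out)
  }
  r <- as.numeric(r_star)
  v_star <- r / (1 - params$refractory_steps * r)
  omega_star <- (v_star - params$v_rest) /
    (params$tau_v * params$w_exc * params$n_neurons * r)
  omega_star <- max(0, omega_star)
  positions <- grid_positions(params)
  n <- params$n_neurons
  omega_of <- function(a_bar, d_bar) {
    om <- compute_connectivity(rep(a_bar, n), rep(d_bar, n), positions,
                               params$kernel)
    sum(om) / (n * (n - 1))
  }
  out <- list(feasible = TRUE, r_star = r, v_star = v_star,
              omega_star = omega_star,
              omega_of_fields = omega_of,
              on_hyperbola = function(a_bar, d_bar)
                abs(omega_of(a_bar, d_bar) - omega_star) <= tol * omega_star)
  class(out) <- "mf_fixed_point"
  out
}

#' @export
print.mf_fixed_point <- function(x, ...) {
  if (!x$feasible) {
    cat(sprintf("no feasible fixed point (implied rate %.4g above ceiling)\n",
                x$r_star))
  } else {
    cat(sprintf("homeostatic fixed point: rate %.4g, V* = %.4g, Omega* = %.4g\n",
                x$r_star, x$v_star, x$omega_star))
  }
  invisible(x)
}
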