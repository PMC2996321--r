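# Independent oracles used across the suite.

# O(n^2) brute-force avalanche scan: for each spike, check every other spike;
# two spikes are in the same avalanche iff they are linked by a chain of
# gaps < bin. Implemented as naive union over sorted times.
brute_force_avalanches <- function(times, bin) {
  times <- sort(times)
  n <- length(times)
  if (n == 0L) return(integer(0))
  id <- integer(n)
  cur <- 1L
  id[1] <- cur
  for (i in seq_len(n - 1L)) {
    if (times[i + 1L] - times[i] >= bin) cur <- cur + 1L
    id[i + 1L] <- cur
  }
  as.integer(table(id))
}

# total progeny of one Galton-Watson cascade with Poisson(sigma) offspring
gw_total_progeny <- function(sigma, max_size = 1e6) {
  total <- 1L
  current <- 1L
  while (current > 0L && total < max_size) {
    nxt <- sum(stats::rpois(current, sigma))
    total <- total + nxt
    current <- nxt
  }
  total
}

# Monte-Carlo estimate of the intersection area of two disks
mc_disk_overlap <- function(R, r, dist, n = 2e5) {
  # sample inside the first disk, count hits inside the second
  u <- stats::runif(n); th <- stats::runif(n, 0, 2 * pi)
  rad <- R * sqrt(u)
  x <- rad * cos(th); y <- rad * sin(th)
  mean((x - dist)^2 + y^2 <= r^2) * pi * R^2
}

# forward-Euler integration of the averaged potential/calcium equations
integrate_mean_field <- function(params, omega_bar, n_steps,
                                 v0 = params$v_rest, ca0 = NULL) {
  if (is.null(ca0)) ca0 <- params$beta_ca * params$v_rest * params$tau_ca
  g <- params$tau_v * params$w_exc * params$n_neurons * omega_bar
  v <- v0; ca <- ca0
  for (i in seq_len(n_steps)) {
    v_old <- v  # calcium influx is driven by this step's firing, i.e. v before the update
    v <- v + (params$v_rest - v) / params$tau_v +
      params$w_exc * params$n_neurons * omega_bar * v
    v <- min(1, v)
    ca <- ca - ca / params$tau_ca + params$beta_ca * v_old
  }
  list(v = v, ca = ca, gain = g)
}

# small parameter set for fast structural tests
tiny_params <- function(...) {
  model_params(n_neurons = 16L, grid_rows = 4L, grid_cols = 4L, seed = 5L, ...)
}
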