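test_that("parameter validation rejects inconsistent settings", {
  expect_error(model_params(n_neurons = 200, grid_rows = 10, grid_cols = 10),
               "grid capacity")
  expect_error(model_params(tau_v = -1), "positive")
  expect_error(model_params(v_rest = 1.2), "v_rest")
  expect_error(model_params(inhib_fraction = 1.5), "inhib_fraction")
})

test_that("initial network has no connections, rest potential and steady calcium", {
  p <- model_params(seed = 3)
  set.seed(3)
  st <- init_network(p)
  expect_true(all(st$omega == 0))
  expect_true(all(st$v == p$v_rest))
  expect_true(all(st$ca == p$beta_ca * p$v_rest * p$tau_ca))
  expect_true(all(st$eps == p$w_exc))
  expect_equal(length(st$inhib_idx), 20L)
  # positions fill the grid row-major with the given spacing
  expect_equal(st$positions[1, ], c(x = 0, y = 0))
  expect_equal(st$positions[2, ], c(x = p$grid_spacing, y = 0))
  expect_equal(st$positions[11, ], c(x = 0, y = p$grid_spacing))
})

test_that("a single-neuron network is degenerate but runs", {
  p <- model_params(n_neurons = 1, grid_rows = 1, grid_cols = 1,
                    inhib_fraction = 0)
  set.seed(1)
  st <- init_network(p)
  expect_equal(dim(st$omega), c(1L, 1L))
  sim <- simulate_network(p, 500, seed = 1, switch = "none")
  expect_equal(nrow(sim$trajectory), 10L)
  expect_true(all(sim$trajectory$v_bar <= 1))
})

test_that("identical seeds give bit-identical runs", {
  p <- tiny_params()
  s1 <- simulate_network(p, 400, seed = 11)
  s2 <- simulate_network(p, 400, seed = 11)
  expect_identical(s1$raster$events, s2$raster$events)
  expect_identical(s1$state$v, s2$state$v)
  expect_identical(s1$trajectory, s2$trajectory)
})

test_that("compiled and reference engines produce bit-identical runs", {
  p <- tiny_params(w_inh = 0.05)
  a <- simulate_network(p, 350, engine = "cpp", seed = 21, record_every = 10)
  b <- simulate_network(p, 350, engine = "r", seed = 21, record_every = 10)
  expect_identical(a$raster$events, b$raster$events)
  expect_equal(a$state$v, b$state$v, tolerance = 1e-14)
  expect_equal(a$state$ca, b$state$ca, tolerance = 1e-14)
  expect_equal(a$state$omega, b$state$omega, tolerance = 1e-12)
  expect_equal(a$trajectory, b$trajectory, tolerance = 1e-12)
})

test_that("unconnected neurons fire like Bernoulli(v_rest) outside refractoriness", {
  # keep fields frozen (rho ~ 0) so omega stays 0; spike probability = v_rest
  p <- model_params(n_neurons = 50, grid_rows = 10, grid_cols = 10,
                    v_rest = 0.05, rho_d = 1e-12, rho_a = 1e-12,
                    inhib_fraction = 0)
  sim <- simulate_network(p, 4000, seed = 2, switch = "none")
  # renewal rate v/(1 + refrac*v)
  expected <- 0.05 / (1 + 4 * 0.05)
  observed <- nrow(sim$raster$events) / (50 * 4000)
  expect_lt(abs(observed - expected) / expected, 0.1)
})

test_that("refractory period blocks spiking for four steps after each spike", {
  p <- model_params(n_neurons = 20, grid_rows = 5, grid_cols = 4,
                    v_rest = 0.5, rho_d = 1e-12, rho_a = 1e-12,
                    inhib_fraction = 0)
  sim <- simulate_network(p, 2000, seed = 8, switch = "none")
  ev <- sim$raster$events
  for (u in unique(ev$unit)) {
    tu <- ev$time[ev$unit == u]
    if (length(tu) > 1) expect_true(all(diff(tu) >= 5))
  }
  # long-run rate cannot exceed 1/(refractory + 1) even at saturation
  p2 <- model_params(n_neurons = 10, grid_rows = 5, grid_cols = 2,
                     v_rest = 0.999, rho_d = 1e-12, rho_a = 1e-12,
                     inhib_fraction = 0)
  sim2 <- simulate_network(p2, 3000, seed = 3, switch = "none")
  expect_lte(max(sim2$trajectory$rate), 0.2)
  expect_gt(mean(sim2$trajectory$rate), 0.18)
})

test_that("membrane potential respects the hard bounds", {
  p <- model_params(regime = "explosive")
  sim <- simulate_network(p, 6000, seed = 5, record_every = 10)
  expect_true(all(sim$trajectory$v_bar <= 1))
  expect_true(all(sim$trajectory$v_bar >= p$v_floor))
  expect_true(all(sim$state$v <= 1))
})

test_that("growth follows the calcium deviation with opposite field signs", {
  p <- tiny_params()
  set.seed(5)
  st <- init_network(p)
  # calcium exactly at target: nothing changes
  st$ca <- rep(p$ca_target, 16)
  st2 <- update_growth(st, p)
  expect_equal(st2$a, st$a)
  expect_equal(st2$d, st$d)
  expect_equal(st2$omega, st$omega)
  # calcium below target: dendrites grow, axons shrink
  st$ca <- rep(p$ca_target - 1, 16)
  st3 <- update_growth(st, p)
  expect_true(all(st3$d > st$d))
  expect_true(all(st3$a < st$a))
  # calcium above target: dendrites shrink, axons grow
  st$ca <- rep(p$ca_target + 1, 16)
  st4 <- update_growth(st, p)
  expect_true(all(st4$d < st$d))
  expect_true(all(st4$a > st$a))
  # radii clip at zero
  st$d <- rep(1e-9, 16); st$ca <- rep(p$ca_target + 100, 16)
  st5 <- update_growth(st, p)
  expect_true(all(st5$d == 0))
})

test_that("inhibitory conversion flips the sampled subset exactly once", {
  p <- model_params(seed = 2)
  set.seed(2)
  st <- init_network(p)
  st2 <- apply_gaba_switch(st, p)
  expect_equal(sum(st2$eps < 0), 20L)
  expect_equal(which(st2$eps < 0), st$inhib_idx)
  expect_true(st2$gaba_switched)
  expect_error(apply_gaba_switch(st2, p), "already")
  # zero fraction: flag set, no neuron converted
  p0 <- model_params(inhib_fraction = 0)
  set.seed(1)
  st0 <- apply_gaba_switch(init_network(p0), p0)
  expect_true(st0$gaba_switched)
  expect_true(all(st0$eps > 0))
})

test_that("inhibition jumps rescale inhibitory weights and validate input", {
  p <- model_params(seed = 4)
  set.seed(4)
  st <- apply_gaba_switch(init_network(p), p)
  same <- apply_inhibition_jump(st, p$w_inh)
  expect_identical(same$eps, st$eps)
  up <- apply_inhibition_jump(st, 0.1)
  expect_equal(sort(unique(up$eps)), c(-0.1, p$w_exc))
  expect_error(apply_inhibition_jump(st, -1), "non-negative")
  set.seed(4)
  fresh <- init_network(p)
  expect_error(apply_inhibition_jump(fresh, 0.1), "conversion")
})

test_that("developmental phases appear in order I, II, III", {
  p <- model_params()
  sim <- simulate_network(p, 60000, seed = 6)
  lab <- detect_phase(sim$trajectory, p)
  runs <- rle(lab)$values
  expect_true(all(runs %in% c("I", "II", "III")))
  expect_identical(runs, sort(unique(runs)))  # no reversal
  expect_true("III" %in% runs)
  # synthetic trajectories
  traj_home <- data.frame(t = 1:50, ca_bar = rep(p$ca_target, 50))
  expect_true(all(detect_phase(traj_home, p) == "III"))
  traj_sub <- data.frame(t = 1:50, ca_bar = seq(0.1, 0.9, length.out = 50) *
                           p$ca_target * 0.5)
  expect_true(all(detect_phase(traj_sub, p) == "I"))
})
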