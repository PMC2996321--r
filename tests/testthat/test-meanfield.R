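test_that("zero connectivity relaxes to the resting potential and proportional calcium", {
  p <- model_params()
  mf <- mean_field_solution(p, 0)
  expect_equal(mf$regime, "zero")
  expect_equal(mf$V_limit, p$v_rest)
  expect_equal(mf$Ca_limit, p$beta_ca * p$tau_ca * p$v_rest)
  expect_false(mf$ca_divergent)
  expect_equal(mf$V_of_t(1e9), p$v_rest, tolerance = 1e-12)
})

test_that("bounded-regime limits increase with density and stay below one", {
  p <- model_params()
  g1 <- 0.3 / (p$tau_v * p$w_exc * p$n_neurons)  # gain 0.3
  g2 <- 0.8 / (p$tau_v * p$w_exc * p$n_neurons)  # gain 0.8
  m0 <- mean_field_solution(p, 0)
  m1 <- mean_field_solution(p, g1)
  m2 <- mean_field_solution(p, g2)
  expect_lt(m0$V_limit, m1$V_limit)
  expect_lt(m1$V_limit, m2$V_limit)
  expect_lt(m2$V_limit, 1)
  expect_lt(m1$Ca_limit, m2$Ca_limit)
})

test_that("supra-unity gain saturates the potential and flags calcium divergence", {
  p <- model_params()
  om <- 1.5 / (p$tau_v * p$w_exc * p$n_neurons)
  mf <- mean_field_solution(p, om)
  expect_equal(mf$regime, "transition")
  expect_equal(mf$V_limit, 1)
  expect_true(mf$ca_divergent)
  expect_identical(mf$Ca_limit, Inf)
  expect_equal(mf$V_of_t(1e6), 1)
})

test_that("closed-form trajectories match direct numerical integration", {
  p <- model_params()
  for (gain in c(0, 0.4, 0.9)) {
    om <- gain / (p$tau_v * p$w_exc * p$n_neurons)
    mf <- mean_field_solution(p, om)
    for (steps in c(200, 2000, 20000)) {
      num <- integrate_mean_field(p, om, steps)
      expect_equal(mf$V_of_t(steps), num$v, tolerance = 1e-6)
      expect_equal(mf$Ca_of_t(steps), num$ca,
                   tolerance = 1e-6 * max(1, num$ca))
    }
  }
})

test_that("steady-state rate follows the calcium balance", {
  p <- model_params(ca_target = 5, beta_ca = 0.5, tau_ca = 1000)
  r <- steady_state_rate(p)
  expect_equal(as.numeric(r), 0.01)
  expect_true(attr(r, "feasible"))
  # doubling the target doubles the rate
  p2 <- model_params(ca_target = 10, beta_ca = 0.5, tau_ca = 1000)
  expect_equal(as.numeric(steady_state_rate(p2)), 0.02)
  # infeasible above the refractory ceiling
  p3 <- model_params(ca_target = 300, beta_ca = 0.5, tau_ca = 1000)
  expect_warning(r3 <- steady_state_rate(p3), "ceiling")
  expect_false(attr(r3, "feasible"))
})

test_that("the nullcline has one branch at zero density and three in the hysteresis region", {
  p <- model_params()
  nc <- nullcline(p, omega_grid = c(0, 0.02, 0.08, 0.5), k = 30)
  expect_true(all(nc$converged))
  at0 <- nc[nc$omega_bar == 0, ]
  expect_equal(nrow(at0), 1L)
  expect_equal(at0$v, p$v_rest, tolerance = 1e-6)
  mid <- nc[nc$omega_bar == 0.08, ]
  expect_equal(nrow(mid), 3L)  # hysteresis: lower, middle, upper
  expect_true(all(nc$n_roots %in% c(1L, 3L)))
  # flat sigmoid: unique root everywhere
  nc0 <- nullcline(p, omega_grid = c(0, 0.02, 0.04), k = 1e-6)
  expect_true(all(nc0$n_roots == 1L))
  # branches are continuous in the density
  dense <- nullcline(p, omega_grid = seq(0.08, 0.2, by = 0.01), k = 30)
  lower <- dense[dense$branch == 1, ]
  expect_true(all(abs(diff(lower$v)) < 0.05))
})

test_that("the homeostatic fixed point intersects the rate condition", {
  p <- model_params()
  fp <- fixed_point(p)
  expect_true(fp$feasible)
  expect_equal(fp$r_star, 0.004)
  # v* inverts the refractory rate relation
  expect_equal(fp$v_star / (1 + p$refractory_steps * fp$v_star), fp$r_star,
               tolerance = 1e-12)
  expect_gt(fp$omega_star, 0)
  # the predicate accepts field pairs that realise omega_star
  om_of <- fp$omega_of_fields
  d_grid <- seq(5, 12, by = 0.05)
  vals <- sapply(d_grid, function(dd) om_of(3.5, dd))
  best <- d_grid[which.min(abs(vals - fp$omega_star))]
  expect_true(fp$on_hyperbola(3.5, best))
  expect_false(fp$on_hyperbola(3.5, best + 3))
  # infeasible parameters give a clean report
  p3 <- model_params(ca_target = 300)
  fp3 <- suppressWarnings(fixed_point(p3))
  expect_false(fp3$feasible)
  expect_true(is.na(fp3$omega_star))
})

test_that("different initial conditions reach the same connectivity but different field splits", {
  # two developments with different initial field radii end near one
  # mean density (the fixed point) while the axonal/dendritic balance differs
  p1 <- model_params(a_init = 5, d_init = 1)
  p2 <- model_params(a_init = 7, d_init = 2.5)
  s1 <- simulate_network(p1, 70000, seed = 17)
  s2 <- simulate_network(p2, 70000, seed = 18)
  tail_mean <- function(s, col) {
    tr <- s$trajectory; n <- nrow(tr)
    mean(tr[[col]][seq(n - n %/% 5, n)])
  }
  om1 <- tail_mean(s1, "omega_bar"); om2 <- tail_mean(s2, "omega_bar")
  expect_lt(abs(om1 - om2) / om1, 0.45)
  split1 <- tail_mean(s1, "a_bar") / tail_mean(s1, "d_bar")
  split2 <- tail_mean(s2, "a_bar") / tail_mean(s2, "d_bar")
  expect_gt(abs(split1 - split2) / split1, 0.1)
})
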