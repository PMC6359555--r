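test_that("free flight on a flat surface is exact", {
  # a torsion surface with zero amplitudes is identically flat
  sys <- toy_system("torsion_surface", A1 = 0, A2 = 0)
  cfg <- integrator_config(dt = 0.01, temperature = 300, friction = 0, seed = 1)
  rng <- make_rng(1, "thermostat")
  st <- list(q = c(0.3, -0.2), p = c(0.5, 1.5), t = 0)
  out <- langevin_step(st, sys, c(0, 0), cfg, rng)
  expect_identical(out$p, st$p)
  expect_identical(out$q, st$q + st$p / 1 * 0.01)
  expect_equal(out$t, 0.01)
})

test_that("NVE energy drift is small over 1e4 steps", {
  sys <- toy_system("double_well_1d")
  cfg <- integrator_config(dt = 1e-3, temperature = 300, friction = 0, seed = 2)
  tr <- run_trajectory(sys, cfg, n_steps = 1e4, stride = 10,
                       q0 = 0.55, p0 = 0.8)
  E <- tr$data$V + tr$data$KE
  expect_lt(max(abs(E - E[1])) / E[1], 1e-4)
})

test_that("instantaneous temperature follows the equipartition definition", {
  expect_equal(instantaneous_temperature(list(p = c(0, 0, 0)), 1, 3), 0)
  # single particle, 1D: KE = kB*300/2  =>  300 K
  p <- sqrt(2 * 1 * kB() * 300 / 2)
  expect_equal(instantaneous_temperature(p, masses = 1, dimension = 1), 300)
  # Maxwell-Boltzmann draw at 350 K, 1e4 particles
  set.seed(5)
  m <- 18
  pp <- rnorm(1e4, sd = sqrt(m * kB() * 350))
  # sampling tolerance: 3 x the standard error T sqrt(2/n) of the estimator
  expect_equal(instantaneous_temperature(pp, masses = rep(m, 1e4),
                                         dimension = 1), 350,
               tolerance = 3 * sqrt(2 / 1e4))
  expect_error(instantaneous_temperature(numeric(0), numeric(0)), "zero degrees")
})

test_that("thermostatted sampling holds the target kinetic temperature", {
  sys <- make_bead_chain(8)
  cfg <- integrator_config(dt = 0.002, temperature = 300, friction = 2, seed = 3)
  tr <- run_trajectory(sys, cfg, n_steps = 1e5, stride = 20)
  d <- tr$data[tr$data$t > 50, ] # discard equilibration from the cold start
  Tbar <- mean(2 * d$KE / (24 * kB()))
  expect_equal(Tbar, 300, tolerance = 0.02)
})

test_that("zero steps returns only the initial state", {
  sys <- toy_system("double_well_1d")
  tr <- run_trajectory(sys, integrator_config(seed = 1), n_steps = 0)
  expect_equal(nrow(tr$data), 1)
  expect_equal(tr$data$t, 0)
})

test_that("run_trajectory without bias is bit-identical to looping langevin_step", {
  sys <- toy_system("double_well_2d")
  cfg <- integrator_config(dt = 0.002, temperature = 300, friction = 2, seed = 17)
  n <- 500
  tr <- run_trajectory(sys, cfg, n_steps = n, stride = 1)
  rng <- make_rng(17, "thermostat")
  st <- list(q = sys$q0, p = c(0, 0), t = 0)
  Q <- matrix(NA_real_, n + 1, 2); P <- matrix(NA_real_, n + 1, 2)
  Q[1, ] <- st$q; P[1, ] <- st$p
  for (i in seq_len(n)) {
    st <- langevin_step(st, sys, c(0, 0), cfg, rng)
    Q[i + 1, ] <- st$q; P[i + 1, ] <- st$p
  }
  expect_identical(unname(tr$q), Q)
  expect_identical(unname(tr$p), P)
})

test_that("zero coupling reproduces the unbiased trajectory bit-for-bit", {
  sys <- toy_system("double_well_1d")
  cfg <- integrator_config(dt = 0.002, temperature = 300, friction = 2, seed = 9)
  plain <- run_trajectory(sys, cfg, n_steps = 2000, stride = 5)
  zero <- run_trajectory(sys, cfg, n_steps = 2000, stride = 5,
                         bias = bias_params(beta_md = 0, beta_prime = 0))
  expect_identical(plain$q, zero$q)
  expect_identical(plain$p, zero$p)
  expect_identical(plain$data$V, zero$data$V)
  # and the bias machinery ran (hills were deposited) without touching forces
  expect_gt(nrow(zero$hills), 0)
})

test_that("reported potential energy never contains the bias", {
  sys <- toy_system("double_well_1d")
  cfg <- integrator_config(seed = 4)
  tr <- run_trajectory(sys, cfg, n_steps = 5000, bias = study_bias_params(),
                       stride = 10)
  V_direct <- vapply(tr$data$q_1, function(x) system_energy(sys, x), numeric(1))
  expect_equal(tr$data$V, V_direct, tolerance = 1e-12)
})

test_that("window lengths shorter than the timestep are rejected", {
  sys <- toy_system("double_well_1d")
  cfg <- integrator_config(dt = 0.002, seed = 1)
  expect_error(run_trajectory(sys, cfg, 100, bias = bias_params(tau1 = 1e-4)),
               "timestep|>= dt")
})

test_that("biased double-well escape is faster than unbiased (paired runs)", {
  sys <- toy_system("double_well_1d")
  taus <- vapply(1:6, function(j) {
    cfg <- integrator_config(seed = 400 + j)
    tu <- run_trajectory(sys, cfg, n_steps = 2e5, stride = 10)
    tb <- run_trajectory(sys, cfg, n_steps = 2e5, stride = 10,
                         bias = study_bias_params())
    c(transition_times(tu$data$t, tu$data$q_1)$tau,
      transition_times(tb$data$t, tb$data$q_1)$tau)
  }, numeric(2))
  p <- t.test(log(taus[1, ]), log(taus[2, ]), paired = TRUE,
              alternative = "greater")$p.value
  expect_lt(p, 0.05)
})
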