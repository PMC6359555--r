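test_that("sigma advances by prefix sums of the scalar increments", {
  st <- new_sigma_state(2, 3, dimension = 2)
  st0 <- update_sigma(st, c(0, 0, 0), st$chain)
  expect_equal(st0$sigma, matrix(0, 2, 3))
  # constant increment c per step over n steps
  for (i in 1:7) st <- update_sigma(st, c(0.1, -0.2, 0.3), st$chain)
  expect_equal(st$sigma, matrix(rep(7 * c(0.1, -0.2, 0.3), each = 2), 2, 3))
  # random sequence against an explicit prefix-sum oracle
  set.seed(61)
  incs <- matrix(rnorm(60), 20, 3)
  st <- new_sigma_state(1, 3)
  for (i in 1:20) st <- update_sigma(st, incs[i, ], st$chain)
  expect_equal(as.numeric(st$sigma), colSums(incs))
})

test_that("hills are deposited per ladder schedule", {
  sched <- build_bias_schedule(2, 1, 2.5, dt = 0.5)
  st <- new_sigma_state(2, 4)
  h <- new_gaussian_history(2, 4, delta_sigma = 0.1)
  # at t = 5 both i = 1 (second hill) and i = 2 (first hill) are due
  h <- deposit_hill(h, st, t = 2.5, schedule = sched)
  h <- deposit_hill(h, st, t = 5, schedule = sched)
  n_hills <- vapply(h$centers, length, integer(1))
  expect_equal(n_hills, rep(c(2L, 1L), each = 4)) # (i=1, k=1..4), (i=2, k=1..4)
  expect_error(deposit_hill(h, st, t = 3, schedule = sched), "boundary")
  # when every ladder aligns, exactly n_r * n centers are appended
  h2 <- deposit_hill(new_gaussian_history(2, 4, delta_sigma = 0.1), st, t = 5)
  expect_equal(sum(vapply(h2$centers, length, integer(1))), 2 * 4)
  # long run: per-(i,k) hill count = floor(t_total / tau2ik)
  sys <- toy_system("double_well_1d")
  tr <- run_trajectory(sys, integrator_config(seed = 6), n_steps = 10000,
                       bias = bias_params(n_r = 3, tau1 = 1, tau2 = 2.5),
                       stride = 100)
  t_total <- 10000 * 0.002
  for (i in 1:3) {
    cnt <- sum(tr$hills$i == i)
    expect_equal(cnt, floor(t_total / (i * 2.5)))
  }
})

test_that("hill force matches the Gaussian derivative", {
  h <- new_gaussian_history(1, 1, W = 0.1, delta_sigma = 1)
  expect_equal(hill_force(h, 3.2, 1, 1), 0)
  st <- new_sigma_state(1, 1)
  st$sigma[1, 1] <- 2
  h <- deposit_hill(h, st, t = 1)
  expect_equal(hill_force(h, 2, 1, 1), 0) # stationary at the center
  f <- hill_force(h, 2 + 1, 1, 1)
  expect_equal(abs(f), 0.1 * exp(-0.5), tolerance = 1e-12)
  expect_gt(f, 0) # pushes sigma away from the visited center
  # finite-difference oracle on random histories of up to 100 hills
  set.seed(71)
  for (rep in 1:10) {
    nh <- sample(1:100, 1)
    hh <- new_gaussian_history(1, 1, W = 0.1, delta_sigma = 0.3)
    sst <- new_sigma_state(1, 1)
    for (c in rnorm(nh, sd = 2)) {
      sst$sigma[1, 1] <- c
      hh <- deposit_hill(hh, sst, t = 1)
    }
    s0 <- rnorm(1, sd = 2)
    eps <- 1e-6
    fd <- -(hill_potential(hh, s0 + eps, 1, 1) -
              hill_potential(hh, s0 - eps, 1, 1)) / (2 * eps)
    expect_equal(hill_force(hh, s0, 1, 1), fd, tolerance = 1e-8)
  }
})

test_that("the sigma-space potential is translation covariant and monotone", {
  set.seed(81)
  centers <- rnorm(20)
  mk <- function(cs) {
    h <- new_gaussian_history(1, 1, W = 0.1, delta_sigma = 0.5)
    st <- new_sigma_state(1, 1)
    for (c in cs) { st$sigma[1, 1] <- c; h <- deposit_hill(h, st, t = 1) }
    h
  }
  h <- mk(centers); hs <- mk(centers + 3.7)
  for (s in rnorm(10))
    expect_equal(hill_force(h, s, 1, 1), hill_force(hs, s + 3.7, 1, 1),
                 tolerance = 1e-12)
  # revisiting the same neighborhood strictly raises the repulsive wall
  h1 <- mk(rep(0, 1)); h2 <- mk(rep(0, 2)); h3 <- mk(rep(0, 3))
  at <- 0.4
  expect_gt(hill_potential(h2, at, 1, 1), hill_potential(h1, at, 1, 1))
  expect_gt(hill_potential(h3, at, 1, 1), hill_potential(h2, at, 1, 1))
})

test_that("well-tempered deposits shrink with accumulated bias", {
  h <- new_gaussian_history(1, 1, W = 0.1, delta_sigma = 0.5, delta_e = 1,
                            well_tempered = TRUE)
  st <- new_sigma_state(1, 1)
  h <- deposit_hill(h, st, t = 1)
  expect_equal(h$weights[[1]][1], 0.1) # first hill at full height
  h <- deposit_hill(h, st, t = 2)
  expect_equal(h$weights[[1]][2], 0.1 * exp(-0.1 / 1), tolerance = 1e-12)
})

test_that("sigma chain rule contracts Phi against the chain vectors", {
  chain <- matrix(c(1, 0, 0, 2), 2, 2, byrow = TRUE)
  phi <- matrix(0, 3, 2)
  expect_equal(sigma_chain_rule(phi, chain), matrix(0, 2, 2))
  phi1 <- matrix(c(2, 0), 1, 2)
  chain1 <- matrix(c(1, 0, 0, 0, 0, 0), 2, 3, byrow = TRUE)
  out <- sigma_chain_rule(phi1, chain1)
  expect_equal(out, matrix(c(2, 0, 0, 0, 0, 0), 2, 3, byrow = TRUE))
  # random tensor-contraction oracle
  set.seed(91)
  phi <- matrix(rnorm(12), 4, 3)
  chain <- matrix(rnorm(9), 3, 3)
  out <- sigma_chain_rule(phi, chain)
  oracle <- t(vapply(1:3, function(k) sum(phi[, k]) * chain[k, ], numeric(3)))
  expect_equal(out, oracle)
  expect_error(sigma_chain_rule(phi, chain, chain_time = 1, phi_time = 2),
               "stale")
})
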