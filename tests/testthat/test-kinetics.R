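test_that("transition detection counts dwell-confirmed crossings", {
  # square wave of period 2T crossing each T
  t <- seq(0, 100, by = 0.1)
  sq <- ifelse(floor(t / 5) %% 2 == 0, -1, 1)
  tt <- transition_times(t, sq, threshold = 0, dwell = 1)
  expect_equal(tt$tau, 5, tolerance = 0.05)
  # single crossing at t = 5 from a start in the lower region
  t2 <- seq(0, 10, by = 0.01)
  v2 <- ifelse(t2 < 5, -1, 1)
  tt2 <- transition_times(t2, v2, dwell = 1)
  expect_equal(tt2$n_events, 1L)
  expect_equal(tt2$tau, 5)
  # a spike shorter than the dwell window is never two events
  v3 <- rep(-1, length(t2)); v3[t2 >= 3 & t2 < 3.2] <- 1
  tt3 <- transition_times(t2, v3, dwell = 1)
  expect_equal(tt3$n_events, 0L)
  # no transitions: explicit result, not NaN
  tt4 <- transition_times(t2, rep(-1, length(t2)))
  expect_true(is.na(tt4$tau))
  expect_equal(tt4$n_events, 0L)
  # telegraph process with known switching rate
  set.seed(151)
  rate <- 0.2
  waits <- rexp(1000, rate)
  ev <- cumsum(waits)
  tg <- seq(0, max(ev) + 1, by = 0.05)
  state <- 2 * (findInterval(tg, ev) %% 2) - 1
  tt5 <- transition_times(tg, state, dwell = 0.0)
  se <- (1 / rate) / sqrt(tt5$n_events)
  expect_lt(abs(tt5$tau - 1 / rate), 2 * se)
})

test_that("Arrhenius fits recover published and synthetic activation energies", {
  tabs <- dialanine_transition_times()
  md <- tabs[tabs$series == "md", ]
  fit <- arrhenius_fit(md$temperature_K, md$tau_ps)
  expect_equal(fit$Ea, 21.05, tolerance = 0.02)
  path <- tabs[tabs$series == "path", ]
  expect_equal(arrhenius_fit(path$temperature_K, path$tau_ps)$Ea, 18.77,
               tolerance = 0.02)
  pc <- tabs[tabs$series == "pc", ]
  expect_equal(arrhenius_fit(pc$temperature_K, pc$tau_ps)$Ea, 9.2,
               tolerance = 0.02)
  # machine-precision inverse on noiseless Arrhenius data
  Ts <- c(280, 320, 380, 440)
  Ea <- 10; A <- 3
  tau <- 1 / (A * exp(-Ea * 1000 / (8.314 * Ts)))
  fit2 <- arrhenius_fit(Ts, tau)
  expect_equal(fit2$Ea, 10, tolerance = 1e-10)
  expect_equal(fit2$lnA, log(3), tolerance = 1e-10)
  expect_equal(predict(fit2, Ts), 1 / tau, tolerance = 1e-10)
  expect_error(arrhenius_fit(c(300, 300), c(1, 2)), "duplicate")
})

test_that("acceleration factors are simple time ratios", {
  expect_equal(acceleration_factor(5, 5)$rho, 1)
  a <- acceleration_factor(42696, 3873)
  expect_equal(a$rho, 11.02, tolerance = 0.001)
  b <- acceleration_factor(10, 5)
  expect_equal(b$rho, 2)
  expect_equal(b$log_rho, log(2))
  expect_error(acceleration_factor(-1, 5), "positive")
})

test_that("free-energy landscapes follow -ln(P/Pref)", {
  # uniform samples: flat landscape
  x <- rep(seq(0.05, 0.95, by = 0.1), each = 10)
  fel <- free_energy_landscape(x, breaks = seq(0, 1, by = 0.1))
  expect_true(all(abs(fel$delta_F) < 1e-12))
  # two bins with probability ratio e differ by exactly 1 kBT
  n2 <- round(exp(1) * 1000)
  x2 <- c(rep(0.25, n2), rep(0.75, 1000))
  fel2 <- free_energy_landscape(x2, breaks = c(0, 0.5, 1))
  expect_equal(unname(diff(as.numeric(fel2$delta_F))), log(n2 / 1000))
  # duplicating every sample leaves the landscape invariant
  fel2b <- free_energy_landscape(c(x2, x2), breaks = c(0, 0.5, 1))
  expect_equal(as.numeric(fel2b$delta_F), as.numeric(fel2$delta_F))
  # literal minimal-probability reference
  felmin <- free_energy_landscape(x2, breaks = c(0, 0.5, 1), ref = "min")
  expect_true(all(as.numeric(felmin$delta_F) <= 0 + 1e-12))
  expect_equal(max(abs(as.numeric(felmin$delta_F))), log(n2 / 1000))
  expect_warning(free_energy_landscape(rep(0.5, 10), breaks = c(0, 1)),
                 "degenerate")
})

test_that("multi-exponential fits recover known decays", {
  t <- seq(0, 20, by = 0.05)
  # noiseless single exponential to near machine precision
  y <- 1 * exp(-0.5 * t)
  fit <- fit_multiexponential(t, y, M = 1)
  expect_equal(fit$rates, 0.5, tolerance = 1e-8)
  expect_equal(fit$amplitudes, 1, tolerance = 1e-8)
  # constant signal: rate tends to zero, amplitude to the level
  fitc <- fit_multiexponential(t, rep(2.5, length(t)), M = 1)
  expect_lt(fitc$rates, 1e-6)
  expect_equal(fitc$amplitudes, 2.5, tolerance = 1e-6)
  # two modes with 1% noise recovered within 5% over replicate seeds
  ok <- 0
  for (s in 1:20) {
    set.seed(200 + s)
    y2 <- 0.7 * exp(-1.0 * t) + 0.3 * exp(-0.1 * t)
    y2n <- y2 + rnorm(length(t), sd = 0.01)
    f2 <- fit_multiexponential(t, y2n, M = 2, seed = s)
    err <- max(abs(f2$rates - c(1.0, 0.1)) / c(1.0, 0.1),
               abs(f2$amplitudes - c(0.7, 0.3)) / c(0.7, 0.3))
    if (err < 0.05) ok <- ok + 1
  }
  expect_gte(ok, 19)
})

test_that("dipole statistics match closed forms", {
  M <- matrix(rep(c(0.1, 0.2, 0.3), each = 50), 50, 3)
  ds <- dipole_statistics(M, volume = 10, temperature = 300, max_lag = 10)
  expect_true(all(abs(ds$acf - 1) < 1e-12))
  expect_equal(ds$eps0_estimate, 1)
  # rotating dipole: raw autocorrelation is the cosine envelope
  tt <- seq(0, 20, by = 0.1)
  Mz <- cbind(0, 0, cos(2 * tt))
  ds2 <- dipole_statistics(Mz, 10, 300, max_lag = 50)
  expect_equal(ds2$acf, cos(2 * 0.1 * (0:50)), tolerance = 0.02)
  # i.i.d. Gaussian components: fluctuation formula within 3 sigma
  set.seed(161)
  sdv <- 0.2
  Mg <- matrix(rnorm(3 * 20000, sd = sdv), ncol = 3)
  ds3 <- dipole_statistics(Mg, volume = 27, temperature = 300)
  expected <- 1 + 3 * sdv^2 * 4 * pi * 138.935458 / (3 * 27 * kB() * 300)
  # var of the variance estimator: 2 sigma^4 / n per component
  se_var <- sqrt(3 * 2 * sdv^4 / 20000)
  se_eps <- se_var * 4 * pi * 138.935458 / (3 * 27 * kB() * 300)
  expect_lt(abs(ds3$eps0_estimate - expected), 3 * se_eps)
})
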