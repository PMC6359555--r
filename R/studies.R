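# Built-in validation studies on the toy systems. These encode the package's
# standard study conditions (system parameters, coupling strengths, run
# lengths) in one place so that tests, the acceptance script, and users run
# the same protocol.

#' Bias settings for the toy-system studies
#'
#' The reference couplings (beta ~ 1e-4) are formulated against the global
#' gradient norm of systems with ~1e5 degrees of freedom; since the global norm
#' scales like sqrt(3N) times a per-atom force, the per-particle bias fraction
#' they realize there is orders of magnitude above 1e-4. For the O(1)-particle
#' toy systems the built-in studies use `beta_prime = 0.2`, `eta_prime = 1`
#' (mean alpha' = 0.1): an order of magnitude below 1, respecting the method's
#' validity condition that the coupling factors stay well below one so the
#' underlying partition is approximately preserved, while the per-particle
#' bias is strong enough to act on desk-scale systems. See the methods
#' vignette. All other parameters keep their reference defaults (`n_r = 5`,
#' `tau1 = 1` ps, `tau2 = 2.5` ps, `gamma_pp = 1e-4`, `W = 0.1` kJ/mol).
#'
#' @param ... overrides passed to [bias_params()].
#' @return a [bias_params()] object.
#' @export
study_bias_params <- function(...) {
  defaults <- list(n_r = 5, tau1 = 1, tau2 = 2.5, beta_md = 1e-4,
                   beta_prime = 0.2, eta_md = 1, eta_prime = 1)
  args <- utils::modifyList(defaults, list(...))
  do.call(bias_params, args)
}

#' Double-well acceleration study
#'
#' Runs paired unbiased/biased trajectories on the 1D double well (a = 5
#' kJ/mol, b = 0.5 nm, T = 300 K) and compares mean transition times between
#' the two wells (threshold 0, dwell-confirmed). The acceleration factor
#' rho = tau_u / tau_b is computed per pair, and a pooled one-sided paired
#' t-test of `log(tau_u) > log(tau_b)` is reported.
#'
#' @param n_pairs number of seed replicate pairs.
#' @param n_steps steps per run.
#' @param seed master seed; pair j uses seed `seed * 1000 + j`.
#' @param temperature temperature (K).
#' @return list with per-pair data frame (`tau_u`, `tau_b`, `rho`), the pooled
#'   `rho` of the pooled mean times, `fraction_accelerated`, and `p_value`.
#' @export
double_well_acceleration_study <- function(n_pairs = 20, n_steps = 600000,
                                           seed = 1, temperature = 300) {
  sys <- toy_system("double_well_1d")
  bias <- study_bias_params()
  res <- data.frame(tau_u = numeric(0), tau_b = numeric(0))
  for (j in seq_len(n_pairs)) {
    sj <- seed * 1000 + j
    cfg <- integrator_config(dt = 0.002, temperature = temperature,
                             friction = 2, seed = sj)
    tu <- run_trajectory(sys, cfg, n_steps = n_steps, stride = 10)
    tb <- run_trajectory(sys, cfg, n_steps = n_steps, bias = bias, stride = 10)
    ttu <- transition_times(tu$data$t, tu$data$q_1, threshold = 0, dwell = 1)
    ttb <- transition_times(tb$data$t, tb$data$q_1, threshold = 0, dwell = 1)
    res <- rbind(res, data.frame(tau_u = ttu$tau, tau_b = ttb$tau))
  }
  ok <- is.finite(res$tau_u) & is.finite(res$tau_b)
  res$rho <- res$tau_u / res$tau_b
  pooled <- acceleration_factor(mean(res$tau_u[ok]), mean(res$tau_b[ok]))
  pv <- stats::t.test(log(res$tau_u[ok]), log(res$tau_b[ok]), paired = TRUE,
                      alternative = "greater")$p.value
  list(pairs = res, rho = pooled$rho,
       fraction_accelerated = mean(res$rho[ok] >= 1),
       p_value = pv, n_pairs = n_pairs, n_steps = n_steps)
}

#' Bead-chain restraint-steering study
#'
#' Runs paired biased trajectories of a 12-bead chain, one with a single
#' crosslink-style restraint (`d0 = 0.75` nm between the chain ends) reweighting
#' the bias and one without, from the extended conformation. Reports the
#' time-averaged restraint violation Delta = d12 - d0 over the last quarter of
#' each run and the paired reduction with its standard error.
#'
#' @param n_seeds number of seed replicates.
#' @param n_steps steps per run.
#' @param seed master seed.
#' @param n_beads chain length.
#' @return list with per-seed data frame (`delta_restrained`,
#'   `delta_unrestrained`), the mean paired `reduction`, its standard error
#'   `se`, and the restraint used.
#' @export
bead_chain_steering_study <- function(n_seeds = 20, n_steps = 200000, seed = 1,
                                      n_beads = 12) {
  sys <- make_bead_chain(n_beads)
  bias <- study_bias_params()
  restr <- structure(list(restraint_record(1, group1 = 0,
                                           group2 = n_beads - 1L,
                                           d0 = 0.75, kind = "xlink")),
                     class = "pathmd_restraints")
  out <- data.frame(delta_restrained = numeric(0),
                    delta_unrestrained = numeric(0))
  for (j in seq_len(n_seeds)) {
    sj <- seed * 1000 + j
    cfg <- integrator_config(dt = 0.002, temperature = 300, friction = 2,
                             seed = sj)
    tr <- run_trajectory(sys, cfg, n_steps = n_steps, bias = bias,
                         restraints = restr, stride = 20)
    tu <- run_trajectory(sys, cfg, n_steps = n_steps, bias = bias,
                         stride = 20)
    last_q <- function(x) x[x$t >= 0.75 * max(x$t), ]
    dr <- mean(last_q(tr$data)$d_r1) - 0.75
    # the unrestrained run carries no d_r column; recompute the distance
    qlast <- last_q(tu$data)
    du <- mean(vapply(seq_len(nrow(qlast)), function(f) {
      qm <- matrix(as.numeric(qlast[f, grep("^q_", names(qlast))]),
                   ncol = 3, byrow = TRUE)
      effective_distance(qm, restr[[1]])$d12
    }, numeric(1))) - 0.75
    out <- rbind(out, data.frame(delta_restrained = dr,
                                 delta_unrestrained = du))
  }
  diffs <- out$delta_unrestrained - out$delta_restrained
  list(per_seed = out, reduction = mean(diffs),
       se = sd(diffs) / sqrt(length(diffs)),
       restraint = restr, n_steps = n_steps)
}

#' Boltzmann-recovery study on the 1D double well
#'
#' (1) A long unbiased Langevin run whose well populations (x > 0 vs x < 0)
#' are compared with the analytic Boltzmann ratio (1 for the symmetric well),
#' with a batch-means standard error. (2) Independent Boltzmann samples drawn
#' by rejection, histogrammed into a free-energy profile and compared per bin
#' with the analytic `V(x)/kBT` (bin-integrated) expectation.
#'
#' @param n_steps MD steps for the population check.
#' @param n_draws independent rejection draws for the profile check.
#' @param seed master seed.
#' @param a,b double-well parameters; `temperature` in K.
#' @return list with `population` (fraction, se, analytic) and `fel`
#'   (data frame: bin mid, observed and expected delta F in kBT, se).
#' @export
boltzmann_recovery_study <- function(n_steps = 1e7, n_draws = 1e6, seed = 1,
                                     a = 5, b = 0.5, temperature = 300) {
  sys <- toy_system("double_well_1d", a = a, b = b)
  cfg <- integrator_config(dt = 0.002, temperature = temperature, friction = 2,
                           seed = seed)
  traj <- run_trajectory(sys, cfg, n_steps = n_steps, stride = 100)
  x <- traj$data$q_1[-1]
  nb <- 20L # batch means for the SE of the correlated series
  batches <- split(x, cut(seq_along(x), nb))
  fr <- vapply(batches, function(v) mean(v > 0), numeric(1))
  population <- list(fraction = mean(x > 0),
                     se = sd(fr) / sqrt(nb),
                     analytic = 0.5)

  # rejection sampling of exp(-V/kBT) on [-2b, 2b] (per-point quartic weight)
  kT <- .kB * temperature
  rng <- make_rng(seed, "fixtures")
  vq <- function(x) a * (x^2 / b^2 - 1)^2
  xs <- numeric(0)
  while (length(xs) < n_draws) {
    u <- rng_draw(rng, 2 * n_draws, FALSE)
    cand <- (u[seq_len(n_draws)] * 4 - 2) * b
    acc <- u[n_draws + seq_len(n_draws)] < exp(-vq(cand) / kT)
    xs <- c(xs, cand[acc])
  }
  xs <- xs[seq_len(n_draws)]
  breaks <- seq(-2 * b, 2 * b, length.out = 41)
  fel <- free_energy_landscape(xs, breaks = breaks, temperature = temperature,
                               ref = "max")
  # exact bin probabilities by fine quadrature of the Boltzmann weight
  fine <- function(lo, hi) {
    g <- seq(lo, hi, length.out = 201)
    w <- exp(-vapply(g, function(x) double_well_potential(x, a, b)$energy,
                     numeric(1)) / kT)
    mean(w) * (hi - lo)
  }
  pexp <- vapply(seq_len(length(breaks) - 1),
                 function(i) fine(breaks[i], breaks[i + 1]), numeric(1))
  pexp <- pexp / sum(pexp)
  dF_exp <- -log(pexp / max(pexp))
  counts <- as.numeric(fel$counts)
  keep <- counts >= 50
  se <- sqrt(1 / pmax(counts, 1) + 1 / max(counts))
  list(population = population,
       fel = data.frame(mid = fel$mids, dF_obs = as.numeric(fel$delta_F),
                        dF_exp = dF_exp, se = se, keep = keep),
       n_steps = n_steps, n_draws = n_draws)
}
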