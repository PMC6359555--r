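# Replays a short biased, restrained engine run step by step with the R-level
# module functions (schedules, action increments, sigma/hill bookkeeping,
# coupling, restrained combination) and checks that the engine applied exactly
# the gradient the modules prescribe.

test_that("the engine loop is reproduced by the module functions", {
  n <- 4; dim <- 3; dof <- n * dim
  n_steps <- 200
  sys <- make_bead_chain(n)
  bias <- bias_params(n_r = 2, tau1 = 0.02, tau2 = 0.05, beta_prime = 0.2,
                      hill_dsigma = 0.1)
  cfg <- integrator_config(dt = 0.002, temperature = 300, friction = 2,
                           seed = 77)
  restr <- structure(list(restraint_record(1, 0, n - 1L, 0.75, "xlink")),
                     class = "pathmd_restraints")
  tr <- run_trajectory(sys, cfg, n_steps = n_steps, bias = bias,
                       restraints = restr, stride = 1, debug = TRUE)
  dbg <- tr$debug
  zlog <- as.data.frame(dbg$zeta_log)
  sched <- build_bias_schedule(2, 0.02, 0.05, 0.002)
  expect_equal(sched$steps1, c(10L, 20L))
  expect_equal(sched$steps2, c(25L, 50L))

  vsum <- array(0, c(2, n, dim))
  g_ab <- array(0, c(2, n, dim))
  sig <- new_sigma_state(2, n, dimension = dim)
  hist <- new_gaussian_history(2, n, W = 0.1, delta_sigma = 0.1)
  as_mat <- function(flat) matrix(flat, ncol = dim, byrow = TRUE)
  max_restr_violation <- 0

  for (step in seq_len(n_steps)) {
    qrow <- tr$q[step, ]; qm <- as_mat(qrow)
    # raw components expected from the module state
    b_ab <- apply(g_ab, c(2, 3), sum)
    phi <- matrix(0, 2, n)
    for (i in 1:2) for (k in 1:n)
      phi[i, k] <- hill_force(hist, sig$sigma[i, k], i, k)
    b_sg <- -sigma_chain_rule(phi, sig$chain)
    expect_lt(max(abs(as.numeric(t(b_ab)) - dbg$bias_ab[step, ])), 1e-12)
    expect_lt(max(abs(as.numeric(t(b_sg)) - dbg$bias_sigma[step, ])),
              1e-10 * max(1, max(abs(b_sg))))
    # coupling and restrained combination
    al <- draw_coupling(bias, xi = c(dbg$xi_md[step], dbg$xi_prime[step]))
    gA <- as_mat(system_gradient(sys, qrow))
    ed <- effective_distance(qm, restr[[1]])
    geo <- list(list(atoms = c(ed$pair[1] + 1, ed$pair[2] + 1),
                     q12 = ed$q12, d12 = ed$d12, d0 = 0.75))
    combo <- combine_restrained_gradients(gA, b_ab, b_sg, al[1], al[2], geo)
    G <- combo - gA
    scale <- max(1, max(abs(G)))
    expect_lt(max(abs(as.numeric(t(G)) - dbg$extra_gradient[step, ])),
              1e-9 * scale)
    # each reweighted bias term never exceeds its unreweighted magnitude:
    # reweighting is cos(Xi) * sign(d - d0) applied per restrained atom
    na_ <- sqrt(sum(gA^2))
    u <- ed$q12 / max(ed$d12, 1e-300)
    for (comp in list(b_ab, b_sg)) {
      nb <- sqrt(sum(comp^2))
      if (nb == 0) next
      t0 <- comp * (al[2] * na_ / nb)
      for (aidx in 1:2) {
        k <- ed$pair[aidx] + 1
        cx <- cos_xi(t0[k, ], u * c(1, -1)[aidx])
        rw <- reweight_restrained_bias(t0[k, ], cx, ed$d12, 0.75)
        v <- sqrt(sum(rw^2)) - sqrt(sum(t0[k, ]^2))
        max_restr_violation <- max(max_restr_violation, v)
      }
    }
    # post-step module updates from the recorded states
    inc <- accumulate_dL(list(q = tr$q[step, ], p = tr$p[step, ]),
                         list(q = tr$q[step + 1, ], p = tr$p[step + 1, ]),
                         dimension = dim)
    sig <- update_sigma(sig, inc$scalar, as_mat(tr$p[step + 1, ]))
    for (i in 1:2) {
      vsum[i, , ] <- vsum[i, , ] + inc$vector
      if (step %% sched$steps1[i] == 0) {
        for (k in 1:n) {
          zeta <- zlog$zeta[zlog$step == step & zlog$i == i & zlog$k == k]
          expect_length(zeta, 1)
          g_ab[i, k, ] <- adaptive_bias_gradient(vsum[i, k, ],
                                                 sched$tau1ik[i], zeta,
                                                 bias$gamma_pp)
        }
        vsum[i, , ] <- 0
      }
      if (step %% sched$steps2[i] == 0) {
        due <- matrix(FALSE, 2, n); due[i, ] <- TRUE
        hist <- deposit_hill(hist, sig, t = step * 0.002, due = due)
      }
    }
  }
  expect_lte(max_restr_violation, 1e-12)
  # the engine's hill log matches the module bookkeeping
  expect_equal(nrow(tr$hills), sum(vapply(hist$centers, length, integer(1))))
  for (i in 1:2) for (k in 1:n) {
    eng <- tr$hills[tr$hills$i == i & tr$hills$k == k, ]
    expect_equal(eng$sigma_center, hist$centers[[(i - 1) * n + k]],
                 tolerance = 1e-12)
  }
})
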