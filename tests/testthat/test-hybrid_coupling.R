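test_that("coupling draws follow alpha = eta beta (1 - xi)", {
  p <- bias_params(beta_md = 1e-4, beta_prime = 2e-4, eta_md = 1, eta_prime = 5)
  a <- draw_coupling(p, xi = c(1, 1))
  expect_equal(unname(a), c(0, 0))
  a <- draw_coupling(p, xi = c(0, 0))
  expect_equal(unname(a), c(1e-4, 1e-3))
  # mean over many draws ~ eta beta / 2
  rng <- make_rng(123, "coupling")
  draws <- t(vapply(1:1e5, function(i) draw_coupling(p, rng = rng), numeric(2)))
  for (j in 1:2) {
    target <- c(1e-4, 1e-3)[j] / 2
    se <- sd(draws[, j]) / sqrt(nrow(draws))
    expect_lt(abs(mean(draws[, j]) - target), 3 * se)
  }
})

test_that("gradient combination renormalizes each bias term to alpha'|grad A|", {
  set.seed(101)
  gA <- rnorm(6); ab <- rnorm(6); sg <- rnorm(6)
  expect_identical(combine_gradients(gA, ab, sg, 0, 0), gA)
  out <- combine_gradients(gA, ab, sg, 0.01, 0.3)
  term_ab <- out - combine_gradients(gA, ab * 0, sg, 0.01, 0.3)
  expect_equal(sqrt(sum(term_ab^2)), 0.3 * sqrt(sum(gA^2)), tolerance = 1e-12)
  # full expression oracle
  oracle <- gA * 1.01 + ab * 0.3 * sqrt(sum(gA^2)) / sqrt(sum(ab^2)) +
    sg * 0.3 * sqrt(sum(gA^2)) / sqrt(sum(sg^2))
  expect_equal(out, oracle)
  # zero-norm bias terms are omitted, not 0/0
  out0 <- combine_gradients(gA, rep(0, 6), sg, 0.01, 0.3)
  expect_true(all(is.finite(out0)))
  expect_equal(out0, gA * 1.01 + sg * 0.3 * sqrt(sum(gA^2)) / sqrt(sum(sg^2)))
})

test_that("principal-component direction is the smallest-eigenvalue mode", {
  set.seed(111)
  # exact diagonal case: component variances (3, 1, 2) -> axis 2
  samp <- rbind(c(sqrt(3), 0, 0), c(-sqrt(3), 0, 0),
                c(0, 1, 0), c(0, -1, 0),
                c(0, 0, sqrt(2)), c(0, 0, -sqrt(2)))
  pc <- principal_component_bias(samp)
  expect_false(pc$fallback)
  expect_equal(pc$direction, c(0, 1, 0))
  # exact isotropic tie: lowest axis, positive sign
  iso <- rbind(diag(3), -diag(3)) # covariance is isotropic
  pc2 <- principal_component_bias(iso)
  expect_equal(pc2$direction, c(1, 0, 0))
  # random 5-dimensional history against a Rayleigh-quotient oracle
  for (rep in 1:5) {
    H <- matrix(rnorm(200 * 5), 200, 5) %*% matrix(rnorm(25), 5, 5)
    pc <- principal_component_bias(H)
    C <- cov(H)
    # oracle: minimize the Rayleigh quotient numerically from many starts
    ray <- function(v) { v <- v / sqrt(sum(v^2)); sum(v * (C %*% v)) }
    best <- Inf; vbest <- NULL
    for (s in 1:20) {
      o <- optim(rnorm(5), ray, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-16))
      if (o$value < best) { best <- o$value; vbest <- o$par }
    }
    vbest <- vbest / sqrt(sum(vbest^2))
    if (vbest[which(vbest != 0)[1]] < 0) vbest <- -vbest
    expect_equal(pc$eigenvalue, best, tolerance = 1e-8)
    expect_lt(max(abs(pc$direction - vbest)), 1e-4)
  }
  # rank-deficient covariance falls back with a warning
  expect_warning(pcf <- principal_component_bias(matrix(0, 10, 3)),
                 "rank-deficient")
  expect_true(pcf$fallback)
})

test_that("cosine overlap behaves at the geometric reference cases", {
  q12 <- c(1, 0, 0)
  expect_equal(cos_xi(c(2, 0, 0), q12), 1)
  expect_equal(cos_xi(c(0, 3, 0), q12), 0)
  expect_equal(cos_xi(c(-1, 0, 0), q12), -1)
  expect_equal(cos_xi(c(0, 0, 0), q12), 0)
  expect_warning(na <- cos_xi(c(1, 0, 0), c(0, 0, 0)), "coincident")
  expect_true(is.na(na))
})

test_that("restraint reweighting never amplifies the bias", {
  b <- c(0.3, -0.4, 0.5)
  expect_equal(reweight_restrained_bias(b, 0.8, 0.75, 0.75), c(0, 0, 0))
  expect_equal(reweight_restrained_bias(b, 1, 1.2, 0.75), b)
  expect_equal(reweight_restrained_bias(b, 0.5, 0.5, 0.75), -0.5 * b)
  set.seed(121)
  for (i in 1:50) {
    b <- rnorm(3); cx <- runif(1, -1, 1)
    out <- reweight_restrained_bias(b, cx, runif(1, 0, 2), 0.75)
    expect_lte(sqrt(sum(out^2)), sqrt(sum(b^2)) + 1e-14)
  }
})

test_that("restrained combination matches a term-by-term oracle", {
  set.seed(131)
  n <- 4; dim <- 3
  gA <- matrix(rnorm(n * dim), n, dim)
  ab <- matrix(rnorm(n * dim), n, dim)
  sg <- matrix(rnorm(n * dim), n, dim)
  # no restraints: exactly the unrestrained combination
  expect_equal(combine_restrained_gradients(gA, ab, sg, 0.01, 0.2),
               matrix(combine_gradients(gA, ab, sg, 0.01, 0.2), n, dim))
  # perpendicular bias on the restrained atoms: only grad_A (1 + alpha_md)
  ab2 <- ab; sg2 <- sg
  ab2[1, ] <- c(0, 1, 0); sg2[1, ] <- c(0, 0, 2)
  ab2[2, ] <- c(0, -3, 0); sg2[2, ] <- c(0, 0, 1)
  geo <- list(list(atoms = c(1, 2), q12 = c(1, 0, 0), d12 = 1.3, d0 = 0.75))
  out <- combine_restrained_gradients(gA, ab2, sg2, 0.01, 0.2, geo)
  expect_equal(out[1, ], gA[1, ] * 1.01)
  expect_equal(out[2, ], gA[2, ] * 1.01)
  # random configuration against explicit recomputation
  for (rep in 1:10) {
    gA <- matrix(rnorm(n * dim), n, dim)
    ab <- matrix(rnorm(n * dim), n, dim)
    sg <- matrix(rnorm(n * dim), n, dim)
    q12 <- rnorm(3); d12 <- runif(1, 0.2, 2); d0 <- 0.75
    geo <- list(list(atoms = c(2, 4), q12 = q12, d12 = d12, d0 = d0))
    out <- combine_restrained_gradients(gA, ab, sg, 0.01, 0.2, geo)
    na <- sqrt(sum(gA^2))
    tab <- ab * (0.2 * na / sqrt(sum(ab^2)))
    tsg <- sg * (0.2 * na / sqrt(sum(sg^2)))
    u <- q12 / sqrt(sum(q12^2)); s <- sign(d12 - d0)
    for (aidx in 1:2) {
      k <- c(2, 4)[aidx]; dsgn <- c(1, -1)[aidx]
      cab <- sum(tab[k, ] * u * dsgn) / sqrt(sum(tab[k, ]^2))
      csg <- sum(tsg[k, ] * u * dsgn) / sqrt(sum(tsg[k, ]^2))
      tab[k, ] <- tab[k, ] * cab * s
      tsg[k, ] <- tsg[k, ] * csg * s
    }
    expect_equal(out, gA * 1.01 + tab + tsg, tolerance = 1e-12)
    # each reweighted bias term never exceeds its unreweighted magnitude
    tab0 <- ab * (0.2 * na / sqrt(sum(ab^2)))
    tsg0 <- sg * (0.2 * na / sqrt(sum(sg^2)))
    for (k in c(2, 4)) {
      expect_lte(sqrt(sum(tab[k, ]^2)), sqrt(sum(tab0[k, ]^2)) + 1e-12)
      expect_lte(sqrt(sum(tsg[k, ]^2)), sqrt(sum(tsg0[k, ]^2)) + 1e-12)
    }
  }
})
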