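# shared oracles: central finite differences and small utilities

fd_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    xp <- x; xm <- x
    xp[j] <- x[j] + h
    xm[j] <- x[j] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

expect_grad_matches_fd <- function(energy_fn, grad, x, tol = 1e-6, h = 1e-5) {
  fd <- fd_gradient(energy_fn, x, h)
  scale <- max(1, max(abs(grad)))
  expect_lt(max(abs(grad - fd)) / scale, tol)
}

# WCA pair energy used as an independent hand-computed reference
wca_pair <- function(r, eps, sig) {
  rc <- sig * 2^(1 / 6)
  if (r >= rc) return(0)
  4 * eps * ((sig / r)^12 - (sig / r)^6) + eps
}
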