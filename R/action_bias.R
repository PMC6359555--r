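# Adaptive-bias component: action-path increments dL = (p + dp) o dq tracked
# per (bias index i, atom k), with the bias gradient re-evaluated at every
# tau1ik window boundary from the windowed increment statistics.

#' Build the ladder of bias coupling times
#'
#' `tau1ik = i * tau1`, `tau2ik = i * tau2` for `i = 1..n_r`, converted to whole
#' step counts by rounding to the nearest step.
#'
#' @param n_r number of parallel biases (>= 1).
#' @param tau1,tau2 base periods (ps), both >= `dt`.
#' @param dt timestep (ps).
#' @return list of class `pathmd_schedule` with `tau1ik`, `tau2ik` (ps,
#'   rounded to step multiples), `steps1`, `steps2` (integer window lengths).
#' @export
build_bias_schedule <- function(n_r, tau1, tau2, dt) {
  stopifnot(n_r >= 1, dt > 0)
  if (tau1 < dt || tau2 < dt) stop("bias periods must be >= dt")
  i <- seq_len(n_r)
  steps1 <- as.integer(round(i * tau1 / dt))
  steps2 <- as.integer(round(i * tau2 / dt))
  structure(list(n_r = as.integer(n_r), tau1 = tau1, tau2 = tau2, dt = dt,
                 tau1ik = steps1 * dt, tau2ik = steps2 * dt,
                 steps1 = steps1, steps2 = steps2),
            class = "pathmd_schedule")
}

#' Action-path increment between two consecutive states
#'
#' `dL(t) = (p(t) + dp(t)) o dq(t)` evaluated elementwise, with
#' `dq = q_curr - q_prev` (minimum-image when a period is supplied),
#' `dp = p_curr - p_prev`, and `p = p_prev`; so the chain weight is simply the
#' updated momentum `p_curr`.
#'
#' @param prev,curr states (lists with `q` and `p`) one step apart.
#' @param dimension per-particle dimension (for reshaping).
#' @param period optional coordinate period for minimum-image displacement.
#' @return list with `vector` (n x dim matrix of elementwise increments) and
#'   `scalar` (per-atom sums).
#' @export
accumulate_dL <- function(prev, curr, dimension = 1, period = NULL) {
  if (length(prev$q) != length(curr$q) || length(prev$p) != length(curr$p) ||
      length(prev$q) != length(prev$p))
    stop("state shapes do not match")
  dq <- curr$q - prev$q
  if (!is.null(period)) dq <- dq - period * round(dq / period)
  dp <- curr$p - prev$p
  v <- (prev$p + dp) * dq
  vm <- matrix(v, ncol = dimension, byrow = TRUE)
  list(vector = vm, scalar = rowSums(vm))
}

#' Adaptive-bias gradient at a window boundary
#'
#' At the close of a `tau1ik` window the frozen gradient for the next window is
#' the window-mean rate of the accumulated elementwise increments, scaled by
#' the fluctuation constant gamma'' and a standard-normal draw zeta:
#' `g = gamma_pp * zeta * window_sum / tau1ik`.
#'
#' @param window_sum accumulated elementwise increment vector (or matrix) over
#'   the closed window.
#' @param tau1ik window length (ps).
#' @param zeta standard-normal draw for this (bias, atom, window).
#' @param gamma_pp fluctuation constant (default 1e-4).
#' @return gradient contribution with the shape of `window_sum`.
#' @export
adaptive_bias_gradient <- function(window_sum, tau1ik, zeta, gamma_pp = 1e-4) {
  stopifnot(tau1ik > 0)
  gamma_pp * zeta * window_sum / tau1ik
}
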