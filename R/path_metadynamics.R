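# Path-sampling component: running path coordinates sigma_ik (prefix sums of
# the scalar action increments) and a history of repulsive Gaussians deposited
# every tau2ik, whose force is mapped back to atoms through the chain vector
# (p + dp).

#' Create an empty sigma state
#'
#' @param n_r number of parallel biases.
#' @param n number of atoms.
#' @param dimension per-particle dimension.
#' @return list of class `pathmd_sigma` with `sigma` (n_r x n matrix) and
#'   `chain` (n x dim matrix of current chain vectors).
#' @export
new_sigma_state <- function(n_r, n, dimension = 1) {
  structure(list(sigma = matrix(0, n_r, n),
                 chain = matrix(0, n, dimension)),
            class = "pathmd_sigma")
}

#' Advance the path coordinates by one step
#'
#' `sigma_ik += dL_k` (the same per-atom scalar increment feeds every bias
#' index) and the chain vector is set to the current `(p + dp)`.
#'
#' @param state a `pathmd_sigma`.
#' @param scalar_dL per-atom scalar increments (length n).
#' @param chain n x dim matrix of current `(p + dp)` vectors.
#' @return the updated state.
#' @export
update_sigma <- function(state, scalar_dL, chain) {
  stopifnot(inherits(state, "pathmd_sigma"))
  if (length(scalar_dL) != ncol(state$sigma))
    stop("scalar increment length does not match atom count")
  state$sigma <- state$sigma + matrix(scalar_dL, nrow(state$sigma),
                                      ncol(state$sigma), byrow = TRUE)
  state$chain <- chain
  state
}

#' Create an empty Gaussian hill history
#'
#' @param n_r number of parallel biases.
#' @param n number of atoms.
#' @param W hill height (kJ/mol).
#' @param delta_sigma hill width (sigma units), > 0.
#' @param delta_e well-tempered scale (kJ/mol).
#' @param well_tempered logical; if `TRUE` each deposit is scaled by
#'   `exp(-Phi_acc/delta_e)` where `Phi_acc` is the accumulated hill potential
#'   at the deposit point.
#' @return list of class `pathmd_hills`.
#' @export
new_gaussian_history <- function(n_r, n, W = 0.1, delta_sigma, delta_e = 1000,
                                 well_tempered = FALSE) {
  stopifnot(delta_sigma > 0)
  centers <- vector("list", n_r * n)
  weights <- vector("list", n_r * n)
  for (j in seq_along(centers)) {
    centers[[j]] <- numeric(0)
    weights[[j]] <- numeric(0)
  }
  structure(list(n_r = as.integer(n_r), n = as.integer(n), W = W,
                 delta_sigma = delta_sigma, delta_e = delta_e,
                 well_tempered = isTRUE(well_tempered),
                 centers = centers, weights = weights,
                 times = rep(list(numeric(0)), n_r * n)),
            class = "pathmd_hills")
}

.hill_idx <- function(history, i, k) (i - 1L) * history$n + k

#' Deposit hills at a tau2 boundary
#'
#' Appends one center per due (bias i, atom k) at the current sigma value.
#'
#' @param history a `pathmd_hills`.
#' @param sigma_state a `pathmd_sigma`.
#' @param t current time (ps).
#' @param due logical n_r x n matrix (or vector over i recycled across atoms)
#'   saying which (i, k) entries are at a `tau2ik` boundary.
#' @param schedule optional `pathmd_schedule`; when given, `due` is derived
#'   from `t` and deposits off-boundary are rejected.
#' @return the updated history.
#' @export
deposit_hill <- function(history, sigma_state, t, due = NULL, schedule = NULL) {
  stopifnot(inherits(history, "pathmd_hills"), inherits(sigma_state, "pathmd_sigma"))
  n_r <- history$n_r; n <- history$n
  if (!is.null(schedule)) {
    steps <- round(t / schedule$dt)
    if (abs(steps * schedule$dt - t) > 1e-9)
      stop("deposit time is not on the step grid")
    due_i <- steps %% schedule$steps2 == 0 & steps > 0
    if (!any(due_i)) stop("deposit requested off every tau2 boundary")
    due <- matrix(due_i, n_r, n)
  } else if (is.null(due)) {
    due <- matrix(TRUE, n_r, n)
  } else if (!is.matrix(due)) {
    due <- matrix(due, n_r, n)
  }
  for (i in seq_len(n_r)) for (k in seq_len(n)) {
    if (!due[i, k]) next
    j <- .hill_idx(history, i, k)
    s <- sigma_state$sigma[i, k]
    w <- history$W
    if (history$well_tempered && history$delta_e > 0) {
      acc <- sum(history$weights[[j]] *
                   exp(-(s - history$centers[[j]])^2 /
                         (2 * history$delta_sigma^2)))
      w <- history$W * exp(-acc / history$delta_e)
    }
    history$centers[[j]] <- c(history$centers[[j]], s)
    history$weights[[j]] <- c(history$weights[[j]], w)
    history$times[[j]] <- c(history$times[[j]], t)
  }
  history
}

#' Force exerted by the deposited hills in sigma space
#'
#' `Phi = sum_c W_c (sigma - sigma_c)/dsigma^2 exp(-(sigma - sigma_c)^2 /
#' (2 dsigma^2))`: minus the sigma-derivative of the accumulated Gaussian
#' potential, i.e. positive when the hills lie below `sigma` (pushing the path
#' coordinate away from visited values).
#'
#' @param history a `pathmd_hills`.
#' @param sigma current sigma value.
#' @param i,k bias and atom index (1-based).
#' @return scalar Phi.
#' @export
hill_force <- function(history, sigma, i, k) {
  stopifnot(inherits(history, "pathmd_hills"))
  if (history$delta_sigma <= 0) stop("hill width must be > 0")
  j <- .hill_idx(history, i, k)
  cs <- history$centers[[j]]
  if (length(cs) == 0) return(0)
  ws <- history$weights[[j]]
  d2 <- history$delta_sigma^2
  sum(ws * (sigma - cs) / d2 * exp(-(sigma - cs)^2 / (2 * d2)))
}

#' Accumulated hill potential in sigma space
#'
#' @inheritParams hill_force
#' @return scalar potential (kJ/mol).
#' @export
hill_potential <- function(history, sigma, i, k) {
  j <- .hill_idx(history, i, k)
  cs <- history$centers[[j]]
  if (length(cs) == 0) return(0)
  sum(history$weights[[j]] *
        exp(-(sigma - cs)^2 / (2 * history$delta_sigma^2)))
}

#' Map sigma-space forces back to atoms
#'
#' Per atom k the contribution is `sum_i Phi_ik * (p + dp)_k`; the engine
#' treats the negative of this as the path-sampling bias gradient so that the
#' applied force repels the path coordinate from deposited hills.
#'
#' @param phi n_r x n matrix of sigma-space forces.
#' @param chain n x dim matrix of current chain vectors `(p + dp)`.
#' @param chain_time,phi_time optional timestamps; a mismatch (stale chain
#'   vectors) is rejected.
#' @return n x dim matrix of per-atom contributions.
#' @export
sigma_chain_rule <- function(phi, chain, chain_time = NULL, phi_time = NULL) {
  if (!is.null(chain_time) && !is.null(phi_time) && chain_time != phi_time)
    stop("stale chain vectors: time mismatch")
  if (ncol(phi) != nrow(chain))
    stop("phi and chain atom counts differ")
  colSums(phi) * chain
}
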