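# Hybrid coupling: renormalizes the two bias gradients against the unbiased
# gradient, optionally rotates them onto principal components, and reweights
# them toward distance restraints through the cosine overlap with the
# restraint vector.

#' Draw the per-step coupling factors
#'
#' `alpha_md = eta_md * beta_md * (1 - xi)` and
#' `alpha' = eta' * beta' * (1 - xi')` with independent uniform draws on
#' `[0, 1)` per step.
#'
#' @param params a [bias_params()] (only the beta/eta fields are used).
#' @param xi optional length-2 vector of uniforms `(xi_md, xi_prime)`; when
#'   `NULL` they are drawn from `rng` (a `"coupling"` stream) or, failing that,
#'   from R's RNG.
#' @param rng optional coupling stream from [make_rng()].
#' @return named vector `c(alpha_md, alpha_prime)`.
#' @export
draw_coupling <- function(params, xi = NULL, rng = NULL) {
  if (is.null(xi)) {
    xi <- if (is.null(rng)) runif(2) else rng_draw(rng, 2, normal = FALSE)
  }
  stopifnot(length(xi) == 2, all(xi >= 0), all(xi <= 1))
  c(alpha_md = params$eta_md * params$beta_md * (1 - xi[1]),
    alpha_prime = params$eta_prime * params$beta_prime * (1 - xi[2]))
}

.gnorm <- function(x) sqrt(sum(x^2))

#' Combine unbiased and bias gradients
#'
#' The total gradient is
#' `grad_A * (1 + alpha_md) + b_ab * alpha' |grad_A|/|b_ab| +
#'  b_sigma * alpha' |grad_A|/|b_sigma|`,
#' with global norms (over all atoms and components); a bias term of zero norm
#' is omitted (no 0/0). After rescaling, each included bias term has global
#' norm `alpha' * |grad_A|` by construction.
#'
#' @param grad_a unbiased gradient (vector or matrix).
#' @param bias_ab,bias_sigma bias gradients with the same shape.
#' @param alpha_md,alpha_prime coupling factors from [draw_coupling()].
#' @return the combined gradient, same shape as `grad_a`.
#' @export
combine_gradients <- function(grad_a, bias_ab, bias_sigma, alpha_md,
                              alpha_prime) {
  na <- .gnorm(grad_a); nab <- .gnorm(bias_ab); nsg <- .gnorm(bias_sigma)
  if (!is.finite(na) || !is.finite(nab) || !is.finite(nsg))
    stop("non-finite gradient norm")
  out <- grad_a * (1 + alpha_md)
  if (nab > 0) out <- out + bias_ab * (alpha_prime * na / nab)
  if (nsg > 0) out <- out + bias_sigma * (alpha_prime * na / nsg)
  out
}

#' Slow-mode principal-component direction
#'
#' Diagonalizes the covariance of a window of bias vectors and returns the
#' unit eigenvector of the smallest eigenvalue (the slowest mode), with the
#' deterministic sign convention that the first nonzero component is positive.
#' Exact ties are broken toward the lowest axis index.
#'
#' @param history matrix with one bias-vector sample per row (>= `ncol`
#'   rows required).
#' @return list with `direction` (unit vector), `eigenvalue`, and
#'   `fallback = TRUE` when the covariance is rank-deficient/degenerate (in
#'   which case `direction` is `NULL` and the caller keeps the raw bias).
#' @export
principal_component_bias <- function(history) {
  history <- as.matrix(history)
  d <- ncol(history)
  if (nrow(history) < d)
    stop("history window must hold at least `dimension` samples")
  C <- stats::cov(history)
  tot <- sum(diag(C))
  if (!is.finite(tot) || tot <= 0) {
    warning("rank-deficient bias covariance; falling back to raw bias")
    return(list(direction = NULL, eigenvalue = NA_real_, fallback = TRUE))
  }
  e <- eigen(C, symmetric = TRUE)
  vals <- e$values
  imin <- which(vals <= min(vals) + 1e-15 * max(abs(vals)))
  if (length(imin) > 1) {
    # tie: pick the candidate eigenvector closest to the lowest axis
    cand <- e$vectors[, imin, drop = FALSE]
    axis_load <- abs(cand[1, ])
    pick <- imin[which.max(axis_load)]
  } else pick <- imin
  v <- e$vectors[, pick[1]]
  first <- which(v != 0)[1]
  if (!is.na(first) && v[first] < 0) v <- -v
  list(direction = v / sqrt(sum(v^2)), eigenvalue = vals[pick[1]],
       fallback = FALSE)
}

#' Cosine overlap between a bias vector and the restraint direction
#'
#' Standard cosine between the bias vector on a restrained atom and the signed
#' restraint direction (`+q12` for the group-1 atom, `-q12` for the group-2
#' atom). A zero bias vector gives cosine 0; coincident restrained atoms
#' (`|q12| = 0`) cannot define a direction and give `NA` with a warning (the
#' engine skips the restraint for that step).
#'
#' @param bias bias vector on the restrained atom.
#' @param q12 restraint vector `q1 - q2` (signed per atom by the caller).
#' @return cosine in `[-1, 1]`, or `NA` for a degenerate restraint.
#' @export
cos_xi <- function(bias, q12) {
  nq <- .gnorm(q12)
  if (nq == 0) {
    warning("coincident restrained atoms: restraint skipped")
    return(NA_real_)
  }
  nb <- .gnorm(bias)
  if (nb == 0) return(0)
  sum(bias * q12) / (nb * nq)
}

#' Reweight a bias vector toward a distance restraint
#'
#' `out = bias * cos(Xi) * sign(d12 - d0)` with `sign(0) = 0` (no bias at exact
#' fulfillment), so `|out| = |cos(Xi)| * |bias| <= |bias|` always. Together
#' with the force convention (force = -gradient) this attracts the restrained
#' atoms when `d12 > d0` and repels them when `d12 < d0`.
#'
#' @param bias bias gradient vector on the restrained atom.
#' @param cosxi cosine overlap from [cos_xi()].
#' @param d12 current restraint distance (nm).
#' @param d0 target distance (nm).
#' @return the reweighted vector.
#' @export
reweight_restrained_bias <- function(bias, cosxi, d12, d0) {
  stopifnot(is.finite(d12), is.finite(d0))
  bias * cosxi * sign(d12 - d0)
}

#' Combine gradients with restraint reweighting
#'
#' Identical to [combine_gradients()] for non-restrained atoms; for atoms in a
#' restraint record each renormalized bias term is reweighted by
#' `cos(Xi) * sign(d12 - d0)` (per atom, against the signed restraint
#' direction) before summation.
#'
#' @param grad_a,bias_ab,bias_sigma per-atom gradient matrices (n rows, dim
#'   columns).
#' @param alpha_md,alpha_prime coupling factors.
#' @param geometries list of restraint geometries, each a list with `atoms`
#'   (1-based indices of the two restrained atoms, group-1 realizing atom
#'   first), `q12`, `d12`, `d0`.
#' @return combined per-atom gradient matrix.
#' @export
combine_restrained_gradients <- function(grad_a, bias_ab, bias_sigma, alpha_md,
                                         alpha_prime, geometries = list()) {
  grad_a <- as.matrix(grad_a)
  bias_ab <- as.matrix(bias_ab); bias_sigma <- as.matrix(bias_sigma)
  na <- .gnorm(grad_a); nab <- .gnorm(bias_ab); nsg <- .gnorm(bias_sigma)
  if (!is.finite(na) || !is.finite(nab) || !is.finite(nsg))
    stop("non-finite gradient norm")
  term_ab <- if (nab > 0) bias_ab * (alpha_prime * na / nab) else bias_ab * 0
  term_sg <- if (nsg > 0) bias_sigma * (alpha_prime * na / nsg) else bias_sigma * 0
  for (g in geometries) {
    if (g$d12 == 0) next # degenerate: skip
    s <- sign(g$d12 - g$d0)
    u <- g$q12 / .gnorm(g$q12)
    dsgn <- c(1, -1)
    for (a in 1:2) {
      k <- g$atoms[a]
      for (term in c("ab", "sg")) {
        m <- if (term == "ab") term_ab else term_sg
        cx <- cos_xi(m[k, ], u * dsgn[a])
        m[k, ] <- m[k, ] * cx * s
        if (term == "ab") term_ab <- m else term_sg <- m
      }
    }
  }
  grad_a * (1 + alpha_md) + term_ab + term_sg
}
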