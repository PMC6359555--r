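# Langevin engine wrappers. The integrator is BAOAB; the bias enters purely as
# an extra gradient (an additional force), never as a reported energy: the V
# column of a trajectory is always the unbiased potential.

#' Integrator configuration
#'
#' @param dt timestep (ps), > 0.
#' @param temperature thermostat temperature (K), >= 0.
#' @param friction Langevin friction gamma (1/ps), >= 0 (0 = NVE).
#' @param seed master integer seed; named child streams (thermostat, coupling,
#'   adaptive, fixtures, init) are derived from it so that toggling one
#'   stochastic component does not shift the others.
#' @return list of class `pathmd_integrator`.
#' @export
integrator_config <- function(dt = 0.002, temperature = 300, friction = 2,
                              seed = 1) {
  stopifnot(dt > 0, temperature >= 0, friction >= 0)
  structure(list(dt = dt, temperature = temperature, friction = friction,
                 seed = as.numeric(seed)),
            class = "pathmd_integrator")
}

#' Deterministic random stream
#'
#' Creates one of the package's named child streams derived from a master seed.
#' Streams: `"thermostat"` (Langevin noise), `"coupling"` (uniform xi draws of
#' the renormalization), `"adaptive"` (normal zeta draws of the adaptive bias),
#' `"fixtures"`, `"init"` (initial momenta).
#'
#' @param seed master integer seed.
#' @param stream stream name.
#' @return an external pointer usable with [langevin_step()] and [rng_draw()].
#' @export
make_rng <- function(seed, stream = c("thermostat", "coupling", "adaptive",
                                      "fixtures", "init")) {
  stream <- match.arg(stream)
  tag <- match(stream, c("thermostat", "coupling", "adaptive", "fixtures",
                         "init"))
  .cpp_make_rng(as.numeric(seed), as.integer(tag))
}

#' @rdname make_rng
#' @param rng stream pointer from [make_rng()].
#' @param n number of draws.
#' @param normal draw standard normals (`TRUE`) or uniforms on `[0,1)`.
#' @export
rng_draw <- function(rng, n, normal = FALSE) .cpp_rng_draw(rng, n, normal)

#' Single BAOAB Langevin step
#'
#' Advances a state by one timestep under total force
#' `-grad V(q) - extra_gradient`, with the extra gradient held fixed across the
#' step. All biasing lives outside the engine and is supplied through
#' `extra_gradient`.
#'
#' @param state list with `q`, `p` (flat vectors) and `t` (ps).
#' @param system a `pathmd_system`.
#' @param extra_gradient flat vector matching `q` (kJ/mol/nm); zero for pure MD.
#' @param config an [integrator_config()].
#' @param rng a `"thermostat"` stream from [make_rng()].
#' @return the advanced state (plus unbiased potential `V`).
#' @export
langevin_step <- function(state, system, extra_gradient, config, rng) {
  stopifnot(inherits(system, "pathmd_system"),
            inherits(config, "pathmd_integrator"))
  if (length(extra_gradient) != length(state$q))
    stop("extra_gradient shape does not match q")
  .cpp_langevin_step(unclass(system), as.numeric(state$q),
                     as.numeric(state$p), state$t,
                     as.numeric(extra_gradient), config$dt,
                     config$temperature, config$friction, rng)
}

#' Instantaneous kinetic temperature
#'
#' `T = 2 KE / (dof kB)` with `KE = sum p^2 / (2 m)`.
#'
#' @param state list with momenta `p`, or a flat momentum vector.
#' @param masses per-particle masses (amu).
#' @param dimension per-particle dimension.
#' @return temperature in K.
#' @export
instantaneous_temperature <- function(state, masses, dimension = 1) {
  p <- if (is.list(state)) state$p else state
  if (!all(is.finite(p))) stop("non-finite momenta")
  dof <- length(p)
  if (dof == 0) stop("zero degrees of freedom")
  if (length(masses) * dimension != dof)
    stop("masses/dimension do not match momenta")
  m <- rep(masses, each = dimension)
  ke <- sum(p^2 / (2 * m))
  2 * ke / (dof * .kB)
}

#' Bias parameters
#'
#' Parameters of the path-dependent bias stack. The ladder of coupling times is
#' `tau1ik = i * tau1`, `tau2ik = i * tau2` for `i = 1..n_r` (periods are
#' rounded to whole step counts). Defaults follow the reference settings:
#' `n_r = 5`, `tau1 = 1` ps, `tau2 = 2.5` ps, `gamma_pp = 1e-4`,
#' `hill_w = 0.1` kJ/mol, `delta_e = 1000` kJ/mol, couplings
#' `beta_md = beta_prime = 1e-4` with fluctuation ranges `eta = 1`.
#'
#' `hill_dsigma = 0` selects the automatic width: 5% of the sigma distance
#' traversed during the first deposition window (clamped to a 1e-8 floor).
#' `well_tempered = TRUE` scales each deposited hill by
#' `exp(-Phi_acc / delta_e)`. `use_pca = TRUE` replaces each atom's bias
#' direction by the smallest-eigenvalue principal component of the recent bias
#' history (window `pca_window`, default `n_r * tau1` ps).
#'
#' @param n_r number of parallel biases (>= 1).
#' @param tau1,tau2 base periods in ps (adaptive-bias window, hill deposition).
#' @param beta_md,beta_prime coupling magnitudes (dimensionless).
#' @param eta_md,eta_prime fluctuation ranges (dimensionless).
#' @param gamma_pp adaptive-bias fluctuation constant gamma''.
#' @param hill_w Gaussian hill height W (kJ/mol).
#' @param hill_dsigma hill width in sigma units (0 = automatic).
#' @param delta_e well-tempered scale (kJ/mol).
#' @param well_tempered logical.
#' @param use_pca logical.
#' @param pca_window principal-component window (ps).
#' @return list of class `pathmd_bias`.
#' @export
bias_params <- function(n_r = 5, tau1 = 1, tau2 = 2.5,
                        beta_md = 1e-4, beta_prime = 1e-4,
                        eta_md = 1, eta_prime = 1,
                        gamma_pp = 1e-4, hill_w = 0.1, hill_dsigma = 0,
                        delta_e = 1000, well_tempered = FALSE,
                        use_pca = FALSE, pca_window = NULL) {
  stopifnot(n_r >= 1, tau1 > 0, tau2 > 0, beta_md >= 0, beta_prime >= 0,
            eta_md >= 0, eta_prime >= 0, gamma_pp >= 0, hill_w >= 0,
            hill_dsigma >= 0)
  if (is.null(pca_window)) pca_window <- n_r * tau1
  structure(list(n_r = as.integer(n_r), tau1 = tau1, tau2 = tau2,
                 beta_md = beta_md, beta_prime = beta_prime,
                 eta_md = eta_md, eta_prime = eta_prime,
                 gamma_pp = gamma_pp, hill_w = hill_w,
                 hill_dsigma = hill_dsigma, delta_e = delta_e,
                 well_tempered = isTRUE(well_tempered),
                 use_pca = isTRUE(use_pca), pca_window = pca_window),
            class = "pathmd_bias")
}

#' Run a (possibly biased, possibly restrained) trajectory
#'
#' Orchestrates the per-step sequence: accumulate the action-path increments
#' dL = (p + dp) o dq, close adaptive-bias windows every `i * tau1`, deposit
#' repulsive Gaussians in the accumulated path coordinate every `i * tau2`,
#' renormalize both bias gradients against the unbiased gradient, optionally
#' rotate them onto principal components, reweight them toward any distance
#' restraints through the cosine overlap with the restraint vector, and
#' integrate with BAOAB. With `bias = NULL` the output is bit-identical to
#' looping [langevin_step()] with the same seed.
#'
#' @param system a `pathmd_system`.
#' @param config an [integrator_config()].
#' @param n_steps number of steps (>= 0).
#' @param bias a [bias_params()] or `NULL` for plain MD.
#' @param restraints a `pathmd_restraints` list or `NULL`.
#' @param stride record every `stride`-th step.
#' @param q0,p0 initial coordinates/momenta (defaults: the system's reference
#'   conformation and zero momenta).
#' @param debug if `TRUE`, capture per-step bias internals (coupling draws,
#'   raw bias vectors, applied extra gradient) for replay tests.
#' @return An object of class `pathmd_trajectory`: list with `data` (a data
#'   frame with columns `t`, `q_*`, `p_*`, `V`, `KE`, `alpha_md`,
#'   `alpha_prime`, `bias_norm_ab`, `bias_norm_sigma` and `d_r<i>` per
#'   restraint), coordinate/momentum matrices `q`, `p`, the hill log, and the
#'   inputs needed to reproduce the run.
#' @export
run_trajectory <- function(system, config, n_steps, bias = NULL,
                           restraints = NULL, stride = 10, q0 = NULL,
                           p0 = NULL, debug = FALSE) {
  stopifnot(inherits(system, "pathmd_system"),
            inherits(config, "pathmd_integrator"))
  if (!is.null(bias)) stopifnot(inherits(bias, "pathmd_bias"))
  dof <- system$n_particles * system$dimension
  if (is.null(q0)) q0 <- system$q0
  if (is.null(p0)) p0 <- rep(0, dof)
  if (!is.null(bias) && (bias$tau1 < config$dt || bias$tau2 < config$dt))
    stop("bias window lengths must not be shorter than the timestep")
  recs <- if (is.null(restraints)) list() else lapply(restraints, unclass)
  raw <- .cpp_run_trajectory(unclass(system), as.numeric(q0), as.numeric(p0),
                             0, config$dt, config$temperature, config$friction,
                             config$seed,
                             if (is.null(bias)) NULL else unclass(bias),
                             recs, as.integer(n_steps), as.integer(stride),
                             isTRUE(debug))
  dim <- system$dimension
  qn <- if (system$n_particles == 1) {
    if (dim == 1) "q_1" else paste0("q_", seq_len(dim))
  } else paste0("q_", rep(seq_len(system$n_particles), each = dim), "_",
                rep(c("x", "y", "z")[seq_len(dim)], system$n_particles))
  pn <- sub("^q", "p", qn)
  colnames(raw$q) <- qn
  colnames(raw$p) <- pn
  data <- data.frame(t = raw$t, raw$q, raw$p, V = raw$V, KE = raw$KE,
                     alpha_md = raw$alpha_md, alpha_prime = raw$alpha_prime,
                     bias_norm_ab = raw$bias_norm_ab,
                     bias_norm_sigma = raw$bias_norm_sigma,
                     check.names = FALSE)
  if (raw$n_restraints > 0) {
    dres <- raw$d_res[, seq_len(raw$n_restraints), drop = FALSE]
    colnames(dres) <- paste0("d_r",
                             vapply(restraints, `[[`, integer(1), "id"))
    data <- cbind(data, dres)
  }
  hills <- as.data.frame(raw$hills)
  out <- list(data = data, q = raw$q, p = raw$p, hills = hills,
              hill_dsigma = raw$hill_dsigma,
              pca_fallbacks = raw$pca_fallbacks,
              system = system, config = config, bias = bias,
              restraints = restraints, n_steps = n_steps, stride = stride)
  if (isTRUE(debug)) out$debug <- raw$debug
  class(out) <- "pathmd_trajectory"
  out
}

#' @export
print.pathmd_trajectory <- function(x, ...) {
  cat(sprintf("<pathmd_trajectory: system '%s', %d steps (stride %d), %s>\n",
              x$system$name, x$n_steps, x$stride,
              if (is.null(x$bias)) "unbiased" else
                sprintf("biased (n_r = %d)", x$bias$n_r)))
  cat(sprintf("  t = [%g, %g] ps, %d frames, %d hill(s) deposited\n",
              min(x$data$t), max(x$data$t), nrow(x$data), nrow(x$hills)))
  invisible(x)
}

#' @export
plot.pathmd_trajectory <- function(x, column = "q_1", ...) {
  graphics::plot(x$data$t, x$data[[column]], type = "l", xlab = "t (ps)",
                 ylab = column, ...)
  invisible(x)
}

#' Write a trajectory as CSV
#'
#' Columns: `t,q_*,p_*,V,KE,alpha_md,alpha_prime,bias_norm_ab,
#' bias_norm_sigma[,d_r<i>]`.
#'
#' @param trajectory a `pathmd_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(trajectory$data, path, row.names = FALSE)
  invisible(path)
}

#' Write a 3D trajectory in XYZ format
#'
#' Standard XYZ: atom-count line, comment line carrying the time, then
#' element-tagged coordinates in Angstrom (nm x 10).
#'
#' @param trajectory a `pathmd_trajectory` of a 3-dimensional system.
#' @param path output path.
#' @param element element tag for every bead.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(trajectory, path, element = "C") {
  sys <- trajectory$system
  if (sys$dimension != 3) stop("XYZ output requires a 3D system")
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nrow(trajectory$q))) {
    writeLines(as.character(sys$n_particles), con)
    writeLines(sprintf("t = %.6f ps", trajectory$data$t[f]), con)
    qm <- matrix(trajectory$q[f, ], ncol = 3, byrow = TRUE) * 10
    writeLines(sprintf("%s %.6f %.6f %.6f", element, qm[, 1], qm[, 2],
                       qm[, 3]), con)
  }
  invisible(path)
}

#' Write the hill log as CSV
#'
#' Columns `t,i,k,sigma_center,W_effective`; enables exact replay of the
#' deposited bias potential.
#'
#' @param trajectory a `pathmd_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hill_log <- function(trajectory, path) {
  utils::write.csv(trajectory$hills, path, row.names = FALSE)
  invisible(path)
}
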