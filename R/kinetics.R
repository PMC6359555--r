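# Kinetic and free-energy analyses: transition times with hysteresis
# (dwell-confirmed) crossing detection, Arrhenius fits, acceleration factors,
# histogram free-energy landscapes, multi-exponential relaxation fits, and
# dipole-fluctuation statistics.

#' Transition times of a scalar order parameter
#'
#' Detects crossings between the regions below and above `threshold` with a
#' dwell confirmation: a crossing counts only once the series has stayed in the
#' destination region for at least `dwell` ps, so a single noisy spike shorter
#' than the dwell window is never counted as two events. The mean transition
#' (waiting) time is the mean of the intervals between the start of the series
#' and the successive confirmed crossings.
#'
#' @param times strictly increasing sample times (ps).
#' @param values order-parameter values.
#' @param threshold region boundary (default 0).
#' @param dwell dwell-confirmation time (ps, default 1).
#' @return list with `tau` (mean transition time, ps), `nu` (= 1/tau, 1/ps),
#'   `n_events`, and `events` (confirmed crossing times). With zero events,
#'   `tau` and `nu` are `NA` and `n_events` is 0 (an explicit "no transitions"
#'   result).
#' @export
transition_times <- function(times, values, threshold = 0, dwell = 1) {
  stopifnot(length(times) == length(values), !is.unsorted(times, strictly = TRUE))
  region <- ifelse(values >= threshold, 1L, -1L)
  cur <- region[1]
  events <- numeric(0)
  i <- 2
  nfr <- length(times)
  while (i <= nfr) {
    if (region[i] != cur) {
      # candidate crossing at times[i]; confirm dwell in the new region
      j <- i
      while (j <= nfr && region[j] == region[i] &&
             times[j] - times[i] < dwell) j <- j + 1
      if (j > nfr || region[j] == region[i]) {
        # dwelled through the window (or series ended while still there and
        # the remaining span reached the window)
        if (j <= nfr || times[nfr] - times[i] >= dwell) {
          events <- c(events, times[i])
          cur <- region[i]
          i <- j
          next
        } else break
      }
      # spike shorter than dwell: skip past it
      i <- j
      next
    }
    i <- i + 1
  }
  if (length(events) == 0)
    return(list(tau = NA_real_, nu = NA_real_, n_events = 0L,
                events = numeric(0), message = "no transitions"))
  waits <- diff(c(times[1], events))
  list(tau = mean(waits), nu = 1 / mean(waits),
       n_events = length(events), events = events)
}

#' Arrhenius fit of transition times
#'
#' Ordinary least squares of `ln(1/tau)` against `1/T`
#' (`ln nu = ln A - Ea/(R T)`); the activation energy is `-slope * R`,
#' reported in kJ/mol with R = 8.314 J/mol/K.
#'
#' @param temperatures temperatures (K), >= 2 distinct values.
#' @param tau transition times (ps), all > 0.
#' @return object of class `arrhenius_fit` with `Ea` (kJ/mol), `lnA`,
#'   `r_squared`, the underlying `lm` fit and the data.
#' @export
arrhenius_fit <- function(temperatures, tau) {
  stopifnot(length(temperatures) == length(tau), length(tau) >= 2,
            all(tau > 0), all(temperatures > 0))
  if (length(unique(temperatures)) < 2)
    stop("duplicate temperatures collapse the design")
  invT <- 1 / temperatures
  lnu <- log(1 / tau)
  fit <- lm(lnu ~ invT)
  R <- 8.314 # J/mol/K
  rsq <- 1 - sum(stats::residuals(fit)^2) / sum((lnu - mean(lnu))^2)
  structure(list(Ea = unname(-coef(fit)[2]) * R / 1000,
                 lnA = unname(coef(fit)[1]),
                 r_squared = rsq,
                 fit = fit,
                 data = data.frame(temperature_K = temperatures, tau_ps = tau)),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit over %d temperatures:\n", nrow(x$data)))
  cat(sprintf("  Ea  = %.3f kJ/mol\n  lnA = %.3f (nu in 1/ps)\n  R^2 = %.4f\n",
              x$Ea, x$lnA, x$r_squared))
  invisible(x)
}

#' @export
coef.arrhenius_fit <- function(object, ...) {
  c(Ea_kJmol = object$Ea, lnA = object$lnA)
}

#' @export
predict.arrhenius_fit <- function(object, temperatures, ...) {
  exp(object$lnA - object$Ea * 1000 / (8.314 * temperatures))
}

#' @export
plot.arrhenius_fit <- function(x, ...) {
  graphics::plot(1 / x$data$temperature_K, log(1 / x$data$tau_ps),
                 xlab = "1/T (1/K)", ylab = "ln nu (1/ps)", ...)
  graphics::abline(x$fit)
  invisible(x)
}

#' Acceleration factor between unbiased and biased kinetics
#'
#' `rho = tau_unbiased / tau_biased` (the ratio of the 2-state transition
#' times), with `ln rho` reported alongside.
#'
#' @param tau_unbiased,tau_biased mean transition times (ps), > 0.
#' @return list of class `pathmd_acceleration` with `rho`, `log_rho` and the
#'   inputs.
#' @export
acceleration_factor <- function(tau_unbiased, tau_biased) {
  if (!is.finite(tau_unbiased) || !is.finite(tau_biased) ||
      tau_unbiased <= 0 || tau_biased <= 0)
    stop("transition times must be positive")
  structure(list(rho = tau_unbiased / tau_biased,
                 log_rho = log(tau_unbiased / tau_biased),
                 tau_unbiased = tau_unbiased, tau_biased = tau_biased),
            class = "pathmd_acceleration")
}

#' @export
print.pathmd_acceleration <- function(x, ...) {
  cat(sprintf("acceleration rho = %.3f (ln rho = %.3f); tau_u = %.4g ps, tau_b = %.4g ps\n",
              x$rho, x$log_rho, x$tau_unbiased, x$tau_biased))
  invisible(x)
}

#' Histogram free-energy landscape
#'
#' `dF = -kB T ln(P / P_ref)` over a 1D or 2D histogram, in kBT units. With
#' the default `ref = "max"` the most probable bin sits at 0 and basins are
#' negative (the usual landscape-plot convention); `ref = "min"` uses the
#' minimal observed probability as reference, making all values >= 0.
#' Empty bins are masked (`NA`).
#'
#' @param samples numeric vector (1D) or 2-column matrix (2D).
#' @param breaks number of bins per axis, or explicit break vectors (list of
#'   two for 2D).
#' @param temperature temperature (K), used only to annotate the kJ/mol scale.
#' @param ref `"max"` or `"min"` probability reference.
#' @return object of class `pathmd_fel` with `mids` (bin centers), `counts`,
#'   `delta_F` (kBT units) and metadata.
#' @export
free_energy_landscape <- function(samples, breaks = 50, temperature = 300,
                                  ref = c("max", "min")) {
  ref <- match.arg(ref)
  two_d <- is.matrix(samples) && ncol(samples) == 2
  if (two_d) {
    bx <- if (is.list(breaks)) breaks[[1]] else
      seq(min(samples[, 1]), max(samples[, 1]), length.out = breaks + 1)
    by <- if (is.list(breaks)) breaks[[2]] else
      seq(min(samples[, 2]), max(samples[, 2]), length.out = breaks + 1)
    cx <- cut(samples[, 1], bx, include.lowest = TRUE)
    cy <- cut(samples[, 2], by, include.lowest = TRUE)
    counts <- table(cx, cy)
    mids <- list(x = (bx[-1] + bx[-length(bx)]) / 2,
                 y = (by[-1] + by[-length(by)]) / 2)
  } else {
    samples <- as.numeric(samples)
    bx <- if (length(breaks) > 1) breaks else
      seq(min(samples), max(samples), length.out = breaks + 1)
    counts <- table(cut(samples, bx, include.lowest = TRUE))
    mids <- (bx[-1] + bx[-length(bx)]) / 2
  }
  counts <- unclass(counts)
  total <- sum(counts)
  if (sum(counts > 0) < 2) {
    warning("all samples fall into one bin: degenerate landscape")
  }
  P <- counts / total
  Pref <- if (ref == "max") max(P) else min(P[P > 0])
  dF <- -log(P / Pref)
  dF[counts == 0] <- NA_real_
  structure(list(mids = mids, counts = counts, delta_F = dF, ref = ref,
                 temperature = temperature, kBT_kJmol = .kB * temperature,
                 n = total),
            class = "pathmd_fel")
}

#' @export
print.pathmd_fel <- function(x, ...) {
  cat(sprintf("<pathmd_fel: %s, %d samples, ref = %s, kBT = %.4g kJ/mol>\n",
              if (is.list(x$mids)) "2D" else "1D", x$n, x$ref, x$kBT_kJmol))
  rng <- range(x$delta_F, na.rm = TRUE)
  cat(sprintf("  delta F range: [%.3f, %.3f] kBT\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
plot.pathmd_fel <- function(x, ...) {
  if (is.list(x$mids)) {
    graphics::image(x$mids$x, x$mids$y, x$delta_F, xlab = "x", ylab = "y", ...)
  } else {
    graphics::plot(x$mids, x$delta_F, type = "b", xlab = "order parameter",
                   ylab = "delta F (kBT)", ...)
  }
  invisible(x)
}

#' Multi-exponential relaxation fit
#'
#' Fits `y(t) = sum_m A_m exp(-k_m t)` by variable projection: the rates are
#' optimized numerically (multi-start quasi-Newton on log-rates) while the
#' amplitudes are solved linearly at each step. Modes are returned sorted by
#' rate, descending.
#'
#' @param times sample times (ps).
#' @param values decay values.
#' @param M number of modes (>= 1).
#' @param n_starts number of random multi-starts.
#' @param seed seed for the multi-start perturbations.
#' @return object of class `pathmd_decay_fit` with `amplitudes`, `rates`
#'   (1/ps), `residual` (RSS), `fitted`, `converged`.
#' @export
fit_multiexponential <- function(times, values, M = 1, n_starts = 10, seed = 1) {
  stopifnot(M >= 1, length(times) == length(values), all(is.finite(values)),
            all(is.finite(times)))
  tspan <- diff(range(times))
  if (tspan <= 0) stop("need a positive time span")
  design <- function(logk) {
    X <- exp(-outer(times, exp(logk)))
    X[!is.finite(X)] <- 0
    X
  }
  rss_of <- function(logk) {
    X <- design(logk)
    fit <- tryCatch(qr.solve(qr(X), values), error = function(e) NULL)
    if (is.null(fit)) return(list(rss = Inf, A = rep(NA_real_, M)))
    r <- values - X %*% fit
    list(rss = sum(r^2), A = as.numeric(fit))
  }
  obj <- function(logk) rss_of(logk)$rss
  # deterministic multi-start grid plus seeded jitter
  u <- rng_draw(make_rng(seed, "fixtures"), n_starts * M, normal = TRUE)
  base <- log(seq(0.5, 2, length.out = M) / tspan * 10)
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- base + u[((s - 1) * M + 1):(s * M)]
    opt <- tryCatch(
      optim(start, obj, method = if (M == 1) "Brent" else "Nelder-Mead",
            lower = if (M == 1) log(1e-12) else -Inf,
            upper = if (M == 1) log(1e12) else Inf,
            control = list(maxit = 2000, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(opt)) next
    # polish with BFGS
    opt2 <- tryCatch(optim(opt$par, obj, method = "BFGS",
                           control = list(maxit = 500, reltol = 1e-15)),
                     error = function(e) opt)
    if (is.null(best) || opt2$value < best$value) best <- opt2
  }
  if (is.null(best))
    stop("multi-exponential fit failed to converge in all restarts")
  sol <- rss_of(best$par)
  k <- exp(best$par)
  ord <- order(k, decreasing = TRUE)
  fitted <- as.numeric(design(best$par) %*% sol$A)
  structure(list(amplitudes = sol$A[ord], rates = k[ord], M = M,
                 residual = sol$rss, fitted = fitted,
                 times = times, values = values,
                 converged = is.finite(sol$rss)),
            class = "pathmd_decay_fit")
}

#' @export
print.pathmd_decay_fit <- function(x, ...) {
  cat(sprintf("multi-exponential fit, M = %d (RSS = %.4g):\n", x$M, x$residual))
  for (m in seq_len(x$M))
    cat(sprintf("  mode %d: A = %.5g, k = %.5g 1/ps (tau = %.5g ps)\n",
                m, x$amplitudes[m], x$rates[m], 1 / x$rates[m]))
  invisible(x)
}

#' @export
coef.pathmd_decay_fit <- function(object, ...) {
  c(stats::setNames(object$amplitudes, paste0("A", seq_len(object$M))),
    stats::setNames(object$rates, paste0("k", seq_len(object$M))))
}

#' Dipole autocorrelation and static-permittivity estimate
#'
#' Computes the raw (non-mean-subtracted) normalized autocorrelation of a total
#' dipole time series by direct summation, and the standard fluctuation
#' estimate of the static permittivity
#' `eps(0) = 1 + (<M^2> - <M>^2) / (3 eps0 V kB T)`
#' in package units (dipole in e nm, volume in nm^3): the prefactor is
#' `4 pi * 138.935458` kJ mol^-1 nm e^-2 for `1/eps0`.
#'
#' @param dipoles matrix of total-dipole samples (frames x components), e nm.
#' @param volume box volume (nm^3).
#' @param temperature temperature (K).
#' @param max_lag maximum autocorrelation lag (frames).
#' @return list with `acf` (normalized, lags 0..max_lag), `eps0_estimate`,
#'   `variance`.
#' @export
dipole_statistics <- function(dipoles, volume, temperature,
                              max_lag = min(200, nrow(dipoles) - 1)) {
  dipoles <- as.matrix(dipoles)
  nf <- nrow(dipoles)
  if (nf < 2) stop("need at least 2 frames")
  denom <- mean(rowSums(dipoles^2))
  acf <- vapply(0:max_lag, function(lag) {
    idx <- seq_len(nf - lag)
    mean(rowSums(dipoles[idx, , drop = FALSE] *
                   dipoles[idx + lag, , drop = FALSE])) / denom
  }, numeric(1))
  mu <- colMeans(dipoles)
  varM <- mean(rowSums(dipoles^2)) - sum(mu^2)
  ke_coul <- 138.935458 # kJ/mol nm e^-2 (Coulomb constant, = 1/(4 pi eps0))
  eps0_est <- if (varM == 0) 1 else
    1 + varM * 4 * pi * ke_coul / (3 * volume * .kB * temperature)
  list(acf = acf, lags = 0:max_lag, eps0_estimate = eps0_est, variance = varM)
}
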