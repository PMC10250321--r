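#' Standard linear solid (SLS) parameter set
#'
#' Bundles the three-element viscoelastic parameters used to describe creep
#' of a cell aspirated into a micropipette: a spring `k1` in parallel with a
#' Maxwell arm (spring `k2` in series with a dashpot `mu`). `k1` and `k2`
#' set the instantaneous and long-time elastic response; `mu` sets the rate
#' of the creep transient.
#'
#' @param k1 Elastic modulus of the parallel spring, Pa. Must be > 0.
#' @param k2 Elastic modulus of the Maxwell-arm spring, Pa. Must be > 0.
#' @param mu Viscous coefficient of the dashpot, Pa·s. Must be > 0.
#'
#' @return An object of class `sls_params`: a named list with elements
#'   `k1`, `k2`, `mu`.
#' @examples
#' p <- sls_params(k1 = 200, k2 = 100, mu = 300)
#' sls_time_constant(p)
#' @export
sls_params <- function(k1, k2, mu) {
  check_positive_scalar(k1, "k1")
  check_positive_scalar(k2, "k2")
  check_positive_scalar(mu, "mu")
  structure(list(k1 = unname(k1), k2 = unname(k2), mu = unname(mu)),
            class = "sls_params")
}

#' @export
print.sls_params <- function(x, ...) {
  cat(sprintf("SLS parameters: k1 = %.6g Pa, k2 = %.6g Pa, mu = %.6g Pa.s (tau = %.6g s)\n",
              x$k1, x$k2, x$mu, sls_time_constant(x)))
  invisible(x)
}

as_sls_params <- function(x) {
  if (inherits(x, "sls_params")) return(x)
  if (is.numeric(x) && length(x) == 3L) return(sls_params(x[[1]], x[[2]], x[[3]]))
  if (is.list(x) && all(c("k1", "k2", "mu") %in% names(x)))
    return(sls_params(x$k1, x$k2, x$mu))
  stop_invalid_parameter("cannot interpret `params` as SLS parameters (need k1, k2, mu)")
}

#' Forward creep model for micropipette aspiration
#'
#' Aspirated length of a cell tongue drawn into a micropipette of radius
#' `rp` under constant pressure `delta_p`, as a function of time, for a
#' standard linear solid regarded as a semi-infinite medium:
#' \deqn{L(t) = \frac{2 R_p \Delta P}{\pi k_1}
#'   \left[1 + \left(\frac{k_1}{k_1+k_2} - 1\right)
#'   \exp\!\left(-\frac{k_1 k_2 t}{\mu (k_1+k_2)}\right)\right]}
#' The response jumps to \eqn{2 R_p \Delta P / (\pi (k_1+k_2))} at t = 0 and
#' creeps exponentially to the plateau [sls_lmax()] with time constant
#' [sls_time_constant()].
#'
#' @param params An [sls_params()] object (or coercible list/3-vector).
#' @param delta_p Aspiration pressure, Pa (>= 0).
#' @param rp Micropipette radius, m (> 0).
#' @param times Numeric vector of times, s (all >= 0).
#'
#' @return Numeric vector of aspirated lengths, m, one per time point;
#'   nondecreasing in `times`.
#' @examples
#' p <- sls_params(200, 100, 300)
#' sls_forward(p, delta_p = 500, rp = 3.5e-6, times = c(0, 4.5, 45))
#' @export
sls_forward <- function(params, delta_p, rp, times) {
  params <- as_sls_params(params)
  if (!is_number(delta_p) || delta_p < 0)
    stop_invalid_parameter("`delta_p` must be a single nonnegative pressure in Pa")
  check_positive_scalar(rp, "rp")
  if (!is.numeric(times) || any(!is.finite(times)))
    stop_domain("`times` must be finite numeric")
  if (any(times < 0)) stop_domain("`times` must be nonnegative")
  ksum <- params$k1 + params$k2
  lmax <- 2 * rp * delta_p / (pi * params$k1)
  lmax * (1 + (params$k1 / ksum - 1) * exp(-params$k1 * params$k2 * times / (params$mu * ksum)))
}

#' Plateau (long-time) aspirated length
#'
#' The t -> Inf limit of [sls_forward()]: `2 * rp * delta_p / (pi * k1)`.
#' The maximum deformation is proportional to 1/k1, so `k1` is identified
#' from the plateau alone.
#'
#' @inheritParams sls_forward
#' @return Maximum aspirated length, m.
#' @export
sls_lmax <- function(params, delta_p, rp) {
  params <- as_sls_params(params)
  if (!is_number(delta_p) || delta_p < 0)
    stop_invalid_parameter("`delta_p` must be a single nonnegative pressure in Pa")
  check_positive_scalar(rp, "rp")
  2 * rp * delta_p / (pi * params$k1)
}

#' Creep time constant of the standard linear solid
#'
#' `mu * (k1 + k2) / (k1 * k2)`, the e-folding time of the exponential
#' transient between the instantaneous jump and the plateau.
#'
#' @inheritParams sls_forward
#' @return Time constant, s.
#' @export
sls_time_constant <- function(params) {
  params <- as_sls_params(params)
  params$mu * (params$k1 + params$k2) / (params$k1 * params$k2)
}

#' Invert the plateau relation for k1
#'
#' Exact inverse of [sls_lmax()]: `k1 = 2 * rp * delta_p / (pi * l_max)`.
#'
#' @param l_max Observed plateau aspirated length, m (> 0).
#' @inheritParams sls_forward
#' @return `k1`, Pa.
#' @export
fit_k1_from_lmax <- function(l_max, delta_p, rp) {
  if (!is_number(l_max) || l_max <= 0) stop_domain("`l_max` must be a single positive length in m")
  check_positive_scalar(delta_p, "delta_p")
  check_positive_scalar(rp, "rp")
  2 * rp * delta_p / (pi * l_max)
}

#' One micropipette-aspiration creep experiment
#'
#' @param delta_p Aspiration pressure, Pa (> 0).
#' @param rp Micropipette radius, m (> 0). The default pipette in the
#'   readers is 3.5 um radius (7 um diameter).
#' @param times Sampling times, s; strictly increasing, first element >= 0,
#'   at least 4 samples (the minimum to identify three parameters).
#' @param lengths Aspirated lengths, m, one per time.
#'
#' @return Object of class `creep_record`.
#' @export
creep_record <- function(delta_p, rp, times, lengths) {
  check_positive_scalar(delta_p, "delta_p")
  check_positive_scalar(rp, "rp")
  if (!is.numeric(times) || !is.numeric(lengths))
    stop_domain("`times` and `lengths` must be numeric")
  if (length(times) != length(lengths))
    stop_domain("`times` and `lengths` must have the same length")
  if (length(times) < 4L)
    stop_domain("a creep record needs at least 4 samples to identify 3 parameters")
  if (any(!is.finite(times)) || any(!is.finite(lengths)))
    stop_domain("`times` and `lengths` must be finite")
  if (times[1] < 0) stop_domain("times must start at >= 0 s")
  if (any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1] + 1L
    stop_domain(sprintf("times must be strictly increasing (violated at sample %d)", bad))
  }
  structure(list(delta_p = delta_p, rp = rp,
                 times = as.numeric(times), lengths = as.numeric(lengths)),
            class = "creep_record")
}

#' @export
print.creep_record <- function(x, ...) {
  cat(sprintf("Creep record: %d samples over [%.3g, %.3g] s, dP = %.4g Pa, Rp = %.3g um\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              x$delta_p, x$rp * 1e6))
  invisible(x)
}

new_sls_fit <- function(params, residual_rms, converged, method,
                        covariance_diag = NULL, details = list()) {
  structure(list(params = params, residual_rms = residual_rms,
                 converged = converged, covariance_diag = covariance_diag,
                 method = method, details = details),
            class = "sls_fit")
}

#' @export
print.sls_fit <- function(x, ...) {
  cat(sprintf("SLS fit (%s)%s\n", x$method, if (x$converged) "" else " [NOT CONVERGED]"))
  if (!is.null(x$params)) {
    cat(sprintf("  k1 = %.6g Pa, k2 = %.6g Pa, mu = %.6g Pa.s\n",
                x$params$k1, x$params$k2, x$params$mu))
  }
  cat(sprintf("  residual RMS = %.3g m\n", x$residual_rms))
  invisible(x)
}

# Log-linear transient regression: fit log(lmax - L) ~ t on points above a
# relative floor, weighted by y^2 (delta-method weights for the log
# transform, so near-plateau points do not dominate through noise
# amplification). Returns tau and the transient amplitude A = lmax - L(0).
transient_loglinear <- function(times, lengths, lmax, transient_floor) {
  y <- lmax - lengths
  ymax <- max(y)
  if (!is.finite(ymax) || ymax <= 0) return(NULL)
  keep <- which(y > transient_floor * ymax)
  if (length(keep) < 3L) return(NULL)
  fit <- stats::lm.wfit(cbind(1, times[keep]), log(y[keep]), w = y[keep]^2)
  slope <- fit$coefficients[2]
  if (!is.finite(slope) || slope >= 0) return(NULL)
  list(tau = -1 / slope, A = exp(fit$coefficients[1]))
}

#' Fit the SLS model by plateau + log-linear transient algebra
#'
#' Deterministic, closed-form-style estimator for aspiration creep. The
#' plateau length is first taken as the mean of the trailing
#' `plateau_fraction` of samples, giving `k1` via [fit_k1_from_lmax()]; the
#' instantaneous length L(0) is back-extrapolated as the intercept of the
#' log-linear regression of `L_max - L(t)` on t (the first frame is too
#' coarse to read the elastic jump directly), giving `k1 + k2` and hence
#' `k2`; the slope of the same regression gives the time constant and hence
#' `mu`. Selecting two transient points recovers the classical two-point
#' algebra exactly; the regression over all transient points is its
#' noise-robust generalization. The plateau estimate is then refined by a
#' short fixed-point iteration (linear fit of L on exp(-t/tau), then redo
#' the regression), which removes the finite-window bias of the trailing
#' mean; on noiseless data this converges to the generating parameters.
#'
#' @param record A [creep_record()].
#' @param plateau_fraction Trailing fraction of samples used for the initial
#'   plateau estimate (default 0.2).
#' @param transient_floor Only samples with `L_max - L(t)` above this
#'   fraction of the transient amplitude enter the log-linear regression
#'   (default 0.05); guards the log transform against plateau noise.
#' @param max_iter,tol Fixed-point refinement controls.
#'
#' @return An `sls_fit` with `method = "two_point"`. If no creep transient
#'   is detectable (flat record) or the trailing window has not plateaued,
#'   the fit is returned with `converged = FALSE` rather than silently
#'   wrong numbers. An `L(0)` back-extrapolation at or above the plateau
#'   raises a degenerate-transient error.
#' @seealso [fit_nls()] for the weighted nonlinear refinement.
#' @export
fit_two_point <- function(record, plateau_fraction = 0.2,
                          transient_floor = 0.05,
                          max_iter = 60L, tol = 1e-12) {
  if (!inherits(record, "creep_record")) stop_domain("`record` must be a creep_record")
  if (!is_number(plateau_fraction) || plateau_fraction <= 0 || plateau_fraction > 0.9)
    stop_invalid_parameter("`plateau_fraction` must be in (0, 0.9]")
  t <- record$times; L <- record$lengths; n <- length(t)

  iw <- seq.int(max(1L, n - max(2L, ceiling(plateau_fraction * n)) + 1L), n)
  lmax <- mean(L[iw])
  tr <- transient_loglinear(t, L, lmax, transient_floor)
  if (is.null(tr)) {
    # Flat record: k1 identifiable from the level, no transient for k2/mu.
    k1 <- fit_k1_from_lmax(max(mean(L), .Machine$double.xmin), record$delta_p, record$rp)
    return(new_sls_fit(NULL, residual_rms = stats::sd(L), converged = FALSE,
                       method = "two_point",
                       details = list(reason = "no creep transient detected",
                                      lmax = lmax, k1_plateau = k1)))
  }

  # Residual-guarded fixed-point refinement: alternate (i) linear fit of L
  # on exp(-t/tau) for (lmax, A) and (ii) the log-linear regression for
  # tau, keeping the lowest-residual state seen. On noiseless data this
  # converges to the generating parameters; under noise the guard stops the
  # plateau/time-constant feedback from drifting.
  state_rss <- function(lmax, tau, A) {
    sum((L - (lmax - A * exp(-t / tau)))^2)
  }
  best <- list(lmax = lmax, tau = tr$tau, A = tr$A,
               rss = state_rss(lmax, tr$tau, tr$A))
  worse <- 0L
  for (iter in seq_len(max_iter)) {
    basis <- exp(-t / tr$tau)
    co <- stats::lm.fit(cbind(1, basis), L)$coefficients
    lmax_new <- co[1]
    if (!is.finite(lmax_new) || lmax_new <= 0) break
    done <- abs(lmax_new - lmax) <= tol * abs(lmax_new)
    lmax <- lmax_new
    tr_new <- transient_loglinear(t, L, lmax, transient_floor)
    if (is.null(tr_new)) break
    tr <- tr_new
    rss <- state_rss(lmax, tr$tau, tr$A)
    if (rss < best$rss) {
      best <- list(lmax = lmax, tau = tr$tau, A = tr$A, rss = rss)
      worse <- 0L
    } else {
      worse <- worse + 1L
      if (worse >= 3L) break
    }
    if (done) break
  }
  lmax <- best$lmax
  tr <- list(tau = best$tau, A = best$A)

  l0 <- lmax - tr$A
  if (l0 >= lmax) stop_domain("degenerate transient: back-extrapolated L(0) >= L_max")
  if (l0 <= 0) {
    return(new_sls_fit(NULL, residual_rms = NA_real_, converged = FALSE,
                       method = "two_point",
                       details = list(reason = "back-extrapolated L(0) <= 0")))
  }
  k1 <- fit_k1_from_lmax(lmax, record$delta_p, record$rp)
  ksum <- fit_k1_from_lmax(l0, record$delta_p, record$rp)
  k2 <- ksum - k1
  if (k2 <= 0) {
    return(new_sls_fit(NULL, residual_rms = NA_real_, converged = FALSE,
                       method = "two_point",
                       details = list(reason = "transient amplitude implies k2 <= 0")))
  }
  mu <- tr$tau * k1 * k2 / ksum
  params <- sls_params(k1, k2, mu)

  resid <- L - sls_forward(params, record$delta_p, record$rp, t)
  rms <- sqrt(mean(resid^2))

  # Plateau acceptance: trailing-window drift must be small against the
  # transient rate scale (lmax - l0) / tau.
  slope_w <- stats::lm.fit(cbind(1, t[iw]), L[iw])$coefficients[2]
  plateaued <- is.finite(slope_w) &&
    abs(slope_w) < 0.01 * (lmax - l0) / tr$tau
  new_sls_fit(params, residual_rms = rms, converged = plateaued,
              method = "two_point",
              details = list(lmax = lmax, l0 = l0, tau = tr$tau,
                             plateau_slope = unname(slope_w),
                             iterations = iter))
}

#' Fit the SLS model by weighted nonlinear least squares
#'
#' Levenberg-Marquardt refinement of the creep fit: minimizes the (optionally
#' weighted) squared residuals of [sls_forward()] against the record over
#' (k1, k2, mu), parameterized on the log scale so positivity is structural.
#' Initialized from [fit_two_point()] unless `init` is given; the returned
#' residual RMS never exceeds that of the initialization.
#'
#' @inheritParams fit_two_point
#' @param init Optional [sls_params()] starting point. Default: the
#'   `two_point` estimate (with a coarse fallback if that fit degenerates).
#' @param weights Optional nonnegative per-sample weights (default uniform).
#'
#' @return An `sls_fit` with `method = "nls"`, including `covariance_diag`,
#'   per-parameter variance estimates from the Jacobian at the optimum
#'   (delta method back to the natural scale). On optimizer failure the
#'   best-so-far parameters are returned with `converged = FALSE`.
#' @export
fit_nls <- function(record, init = NULL, weights = NULL) {
  if (!inherits(record, "creep_record")) stop_domain("`record` must be a creep_record")
  t <- record$times; L <- record$lengths; n <- length(t)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0))
    stop_invalid_parameter("`weights` must be nonnegative, one per sample")
  sw <- sqrt(weights)

  if (is.null(init)) {
    tp <- tryCatch(fit_two_point(record), error = function(e) NULL)
    if (!is.null(tp) && !is.null(tp$params)) {
      init <- tp$params
    } else {
      # Coarse fallback: plateau from last sample, equal springs, tau from
      # a third of the observation window.
      k1 <- fit_k1_from_lmax(max(L[n], .Machine$double.eps), record$delta_p, record$rp)
      init <- sls_params(k1, k1, k1 * max(t[n], 1) / 6)
    }
  } else {
    init <- as_sls_params(init)
  }

  resid_fn <- function(lp) {
    p <- sls_params(exp(lp[1]), exp(lp[2]), exp(lp[3]))
    sw * (sls_forward(p, record$delta_p, record$rp, t) - L)
  }
  lp0 <- log(c(init$k1, init$k2, init$mu))
  out <- minpack.lm::nls.lm(par = lp0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-15, ptol = 1e-15))
  p <- sls_params(exp(out$par[1]), exp(out$par[2]), exp(out$par[3]))
  resid <- sls_forward(p, record$delta_p, record$rp, t) - L
  rms <- sqrt(mean(resid^2))
  converged <- out$info %in% 1:4

  cov_diag <- rep(NA_real_, 3)
  dof <- n - 3
  if (dof > 0) {
    vc <- tryCatch({
      s2 <- sum(out$fvec^2) / dof
      diag(solve(out$hessian)) * s2
    }, error = function(e) rep(NA_real_, 3))
    # delta method: var(exp(lp)) ~ exp(lp)^2 var(lp)
    cov_diag <- vc * c(p$k1, p$k2, p$mu)^2
  }
  names(cov_diag) <- c("k1", "k2", "mu")
  new_sls_fit(p, residual_rms = rms, converged = converged,
              covariance_diag = cov_diag, method = "nls",
              details = list(info = out$info, message = out$message,
                             init = unlist(init[c("k1", "k2", "mu")])))
}
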