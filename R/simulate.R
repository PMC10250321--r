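#' Measurement-noise specification
#'
#' Describes the noise added by a generator. `additive_gaussian` adds
#' i.i.d. Gaussian noise with standard deviation `scale` times the signal
#' ceiling (the maximum absolute clean value), emulating a fixed
#' instrument noise floor; `multiplicative_gaussian` perturbs each sample
#' by a Gaussian factor `1 + scale * z`, emulating proportional error.
#' The default 2% additive level reflects typical optical-tracking and
#' interferometric precision and is a calibration choice, not a measured
#' instrument property.
#'
#' @param kind `"additive_gaussian"` or `"multiplicative_gaussian"`.
#' @param scale Nonnegative noise scale (fraction of signal ceiling for
#'   additive, fractional standard deviation for multiplicative).
#' @param seed Optional integer seed; a given (spec, seed) pair always
#'   produces bit-identical output.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("additive_gaussian", "multiplicative_gaussian"),
                       scale = 0.02, seed = NULL) {
  kind <- match.arg(kind)
  if (!is_number(scale) || scale < 0)
    stop_invalid_parameter("`scale` must be a single nonnegative number")
  if (!is.null(seed) && !is_number(seed))
    stop_invalid_parameter("`seed` must be a single integer or NULL")
  structure(list(kind = kind, scale = scale, seed = seed), class = "noise_spec")
}

apply_noise <- function(clean, noise) {
  if (is.null(noise)) return(clean)
  if (!inherits(noise, "noise_spec")) stop_invalid_parameter("`noise` must be a noise_spec")
  if (noise$scale == 0) return(clean)
  if (!is.null(noise$seed)) set.seed(as.integer(noise$seed))
  z <- stats::rnorm(length(clean))
  switch(noise$kind,
         additive_gaussian = clean + noise$scale * max(abs(clean)) * z,
         multiplicative_gaussian = clean * (1 + noise$scale * z))
}

#' Simulate a micropipette-aspiration creep record
#'
#' Evaluates [sls_forward()] on an even time grid and applies the noise
#' spec. With zero noise the record reproduces the forward model exactly.
#' The generating parameters are attached as the `"ground_truth"`
#' attribute so recovery tests can compare fits against truth.
#'
#' @param params Ground-truth [sls_params()].
#' @inheritParams sls_forward
#' @param n_points Number of samples (>= 4).
#' @param t_max Last sample time, s. Default 10 time constants; a warning
#'   is issued below 5 (the plateau is then poorly constrained).
#' @param noise A [noise_spec()] (default 2% additive).
#' @return A [creep_record()] with `attr(, "ground_truth")`.
#' @export
simulate_creep <- function(params, delta_p = 500, rp = 3.5e-6,
                           n_points = 200, t_max = NULL,
                           noise = noise_spec()) {
  params <- as_sls_params(params)
  if (!is_number(n_points) || n_points < 4)
    abort_cellmech("`n_points` must be at least 4", "cellmech_insufficient_samples")
  tau <- sls_time_constant(params)
  if (is.null(t_max)) t_max <- 10 * tau
  check_positive_scalar(t_max, "t_max")
  if (t_max < 5 * tau)
    warning(sprintf("t_max = %.3g s covers only %.2g time constants; plateau poorly constrained",
                    t_max, t_max / tau))
  times <- seq(0, t_max, length.out = n_points)
  clean <- sls_forward(params, delta_p, rp, times)
  rec <- creep_record(delta_p, rp, times, apply_noise(clean, noise))
  attr(rec, "ground_truth") <- list(params = params, noise = noise, t_max = t_max)
  rec
}

#' Simulate a nanoindentation curve with a pre-contact baseline
#'
#' Builds the canonical depth-controlled indentation recording: a flat
#' zero-load approach segment of `baseline_points` samples over the
#' pre-contact travel `contact_offset`, followed by `n_points` samples of
#' Hertzian loading up to the instrument's controlled depth, then noise.
#' The `"ground_truth"` attribute carries the generating modulus and the
#' exact contact index. In `"raw"` mode the same physics is emitted as
#' (piezo displacement, cantilever deflection) with z = delta + F/k, so
#' [reduce_raw()] recovers the reduced curve exactly.
#'
#' @param e_reduced Ground-truth reduced Young's modulus, Pa.
#' @param instrument An [instrument_config()].
#' @param n_points Loading-segment samples (default 200).
#' @param baseline_points Pre-contact samples (default 50; may be 0).
#' @param contact_offset Pre-contact travel, m (default 0.5 um).
#' @param noise A [noise_spec()] applied to the load channel.
#' @param mode `"reduced"` or `"raw"` output.
#' @return An [indentation_curve()] with `attr(, "ground_truth")`.
#' @export
simulate_indentation <- function(e_reduced, instrument = instrument_config(),
                                 n_points = 200, baseline_points = 50,
                                 contact_offset = 0.5e-6,
                                 noise = noise_spec(), mode = c("reduced", "raw")) {
  mode <- match.arg(mode)
  check_positive_scalar(e_reduced, "e_reduced")
  if (!inherits(instrument, "instrument_config"))
    stop_invalid_parameter("`instrument` must be an instrument_config")
  if (!is_number(n_points) || n_points < 20)
    stop_invalid_parameter("`n_points` must be at least 20")
  if (!is_number(baseline_points) || baseline_points < 0)
    stop_invalid_parameter("`baseline_points` must be >= 0")
  if (!is_number(contact_offset) || contact_offset < 0)
    stop_invalid_parameter("`contact_offset` must be >= 0")
  if (baseline_points > 0 && contact_offset <= 0)
    abort_cellmech("baseline samples requested but contact_offset is 0: degenerate curve",
                   "cellmech_degenerate_curve")
  pos_base <- if (baseline_points > 0)
    seq(0, contact_offset, length.out = baseline_points + 1)[seq_len(baseline_points)]
  else numeric(0)
  pos_load <- seq(contact_offset, contact_offset + instrument$max_depth,
                  length.out = n_points)
  pos <- c(pos_base, pos_load)
  delta <- pmax(pos - contact_offset, 0)
  clean <- hertz_force(e_reduced, instrument$tip_radius, delta)
  load <- apply_noise(clean, noise)
  cur <- if (mode == "reduced") {
    indentation_curve(depth = pos, load = load, mode = "reduced",
                      instrument = instrument)
  } else {
    d <- load / instrument$spring_constant
    indentation_curve(z = pos + d, d = d, mode = "raw",
                      instrument = instrument)
  }
  attr(cur, "ground_truth") <- list(e_reduced = e_reduced,
                                    contact_index = as.integer(baseline_points) + 1L,
                                    contact_offset = contact_offset,
                                    noise = noise)
  cur
}

#' Biased persistent random-walk specification
#'
#' Parameters of the trajectory generator. Each step is the sum of a
#' deterministic drift `drift_fraction * speed_scale * step_time` toward
#' the gradient axis and a random component whose heading follows a
#' first-order autoregressive process with coefficient `persistence`
#' (stationary unit-variance Gaussian per component), scaled so the
#' expected random step length is `(1 - drift_fraction) * speed_scale *
#' step_time`. Expected curvilinear speed is therefore approximately
#' `speed_scale` at both extremes of `drift_fraction` and between them.
#'
#' @param step_time Frame interval, min (default 3, the usual chamber
#'   frame rate).
#' @param duration Track duration, min (default 360, i.e. 6 h).
#' @param speed_scale Target curvilinear speed, um/min.
#' @param drift_fraction Fraction of motion that is deterministic drift
#'   toward the source, in \[0, 1\].
#' @param persistence AR(1) coefficient of the random heading, in \[0, 1).
#' @param seed Optional integer seed.
#' @return Object of class `walk_spec`.
#' @export
walk_spec <- function(step_time = 3, duration = 360, speed_scale = 1,
                      drift_fraction = 0.3, persistence = 0.5, seed = NULL) {
  check_positive_scalar(step_time, "step_time")
  check_positive_scalar(duration, "duration")
  if (!is_number(speed_scale) || speed_scale < 0)
    stop_invalid_parameter("`speed_scale` must be >= 0")
  if (!is_number(drift_fraction) || drift_fraction < 0 || drift_fraction > 1)
    stop_invalid_parameter("`drift_fraction` must be in [0, 1]")
  if (!is_number(persistence) || persistence < 0 || persistence >= 1)
    stop_invalid_parameter("`persistence` must be in [0, 1)")
  structure(list(step_time = step_time, duration = duration,
                 speed_scale = speed_scale, drift_fraction = drift_fraction,
                 persistence = persistence, seed = seed),
            class = "walk_spec")
}

#' Simulate chemotaxis trajectories as biased persistent random walks
#'
#' @param n_cells Number of tracks (>= 1).
#' @param spec A [walk_spec()].
#' @param gradient_axis Direction toward the chemoattractant source.
#' @return List of [trajectory()] objects; each carries
#'   `attr(, "ground_truth")` with the drift fraction.
#' @export
simulate_trajectories <- function(n_cells, spec = walk_spec(),
                                  gradient_axis = c(1, 0)) {
  if (!is_number(n_cells) || n_cells < 1)
    stop_invalid_parameter("`n_cells` must be >= 1")
  if (!inherits(spec, "walk_spec")) stop_invalid_parameter("`spec` must be a walk_spec")
  if (!is.null(spec$seed)) set.seed(as.integer(spec$seed))
  g <- gradient_axis / sqrt(sum(gradient_axis^2))
  n_steps <- max(1L, floor(spec$duration / spec$step_time))
  dt <- spec$step_time
  drift_step <- spec$drift_fraction * spec$speed_scale * dt
  # E|N2(0, I)| = sqrt(pi/2); scale so the mean random step length matches.
  s_rand <- (1 - spec$drift_fraction) * spec$speed_scale * dt * sqrt(2 / pi)
  p <- spec$persistence
  lapply(seq_len(n_cells), function(i) {
    v <- matrix(stats::rnorm(2 * (n_steps + 1)), ncol = 2)
    if (p > 0) {
      for (k in seq_len(n_steps) + 1L)
        v[k, ] <- p * v[k - 1L, ] + sqrt(1 - p^2) * v[k, ]
    }
    steps <- matrix(drift_step * g, n_steps, 2, byrow = TRUE) +
      s_rand * v[-1L, , drop = FALSE]
    xs <- c(0, cumsum(steps[, 1]))
    ys <- c(0, cumsum(steps[, 2]))
    tr <- trajectory(sprintf("cell_%03d", i), seq(0, by = dt, length.out = n_steps + 1),
                     xs, ys, gradient_axis = g)
    attr(tr, "ground_truth") <- list(drift_fraction = spec$drift_fraction,
                                     persistence = p, speed_scale = spec$speed_scale)
    tr
  })
}

#' Simulate labeled cohorts of mechanical measurements
#'
#' Builds the two-group (or k-group) structure of a cell-mechanics
#' experiment: per-cell ground-truth parameters are drawn log-normally
#' around each group mean (`cv` is the coefficient of variation; moduli
#' are positive with heavy right tails, which the log-normal captures),
#' then one synthetic curve is generated per cell. `cv = 0` makes every
#' cell identical to the group mean.
#'
#' @param group_specs Named list; each element is a list with `mean`
#'   (a scalar modulus in Pa for `type = "indentation"`, or an
#'   [sls_params()] for `type = "creep"`), `cv` (>= 0) and `n` (>= 1).
#' @param seed Integer seed driving both the parameter draws and the
#'   per-curve noise.
#' @param type `"indentation"` or `"creep"`.
#' @param noise_scale Per-curve noise scale (see [noise_spec()]).
#' @param noise_kind Noise kind for the per-curve noise.
#' @param ... Further arguments passed to [simulate_indentation()] or
#'   [simulate_creep()].
#' @return Named list (one element per group) of lists of curves/records;
#'   each measurement carries its own ground truth attribute, and each
#'   group carries `attr(, "group_truth")` with the drawn per-cell values.
#' @export
simulate_cohort_mechanics <- function(group_specs, seed = 1,
                                      type = c("indentation", "creep"),
                                      noise_scale = 0.02,
                                      noise_kind = "additive_gaussian", ...) {
  type <- match.arg(type)
  if (is.null(names(group_specs)) || any(names(group_specs) == ""))
    stop_invalid_parameter("`group_specs` must be a named list of groups")
  set.seed(as.integer(seed))
  lnorm_draw <- function(m, cv, n) {
    if (cv == 0) return(rep(m, n))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
  }
  out <- lapply(names(group_specs), function(gname) {
    gs <- group_specs[[gname]]
    if (!is_number(gs$cv) || gs$cv < 0) stop_invalid_parameter("`cv` must be >= 0")
    if (!is_number(gs$n) || gs$n < 1) stop_invalid_parameter("`n` must be >= 1")
    n <- as.integer(gs$n)
    if (type == "indentation") {
      check_positive_scalar(gs$mean, "mean")
      truths <- lnorm_draw(gs$mean, gs$cv, n)
      curves <- lapply(truths, function(e) {
        simulate_indentation(e, noise = noise_spec(noise_kind, noise_scale), ...)
      })
      attr(curves, "group_truth") <- truths
    } else {
      pm <- as_sls_params(gs$mean)
      truths <- cbind(k1 = lnorm_draw(pm$k1, gs$cv, n),
                      k2 = lnorm_draw(pm$k2, gs$cv, n),
                      mu = lnorm_draw(pm$mu, gs$cv, n))
      curves <- lapply(seq_len(n), function(i) {
        simulate_creep(sls_params(truths[i, 1], truths[i, 2], truths[i, 3]),
                       noise = noise_spec(noise_kind, noise_scale), ...)
      })
      attr(curves, "group_truth") <- truths
    }
    curves
  })
  names(out) <- names(group_specs)
  out
}
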