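#' Ferrule-top nanoindenter configuration
#'
#' Instrument constants for a cantilever-based optical-fiber nanoindenter.
#' The defaults match a soft-cell probe: cantilever spring constant
#' 0.048 N/m, spherical tip of 9 um radius, depth-controlled 5 um indents
#' with a 2 s loading/unloading period. Probe datasheets quote a single
#' "9 um" tip size whose radius-vs-diameter convention is ambiguous; the
#' radius interpretation is the default here and a 4.5 um alternate is one
#' argument away, so analyses should state which they pin.
#'
#' @param spring_constant Cantilever spring constant, N/m.
#' @param tip_radius Spherical tip radius, m.
#' @param max_depth Controlled indentation depth, m.
#' @param load_period Loading (and unloading) duration, s.
#'
#' @return Object of class `instrument_config`.
#' @examples
#' instrument_config()                      # 9 um tip radius
#' instrument_config(tip_radius = 4.5e-6)   # diameter interpretation
#' @export
instrument_config <- function(spring_constant = 0.048, tip_radius = 9e-6,
                              max_depth = 5e-6, load_period = 2) {
  check_positive_scalar(spring_constant, "spring_constant")
  check_positive_scalar(tip_radius, "tip_radius")
  check_positive_scalar(max_depth, "max_depth")
  check_positive_scalar(load_period, "load_period")
  structure(list(spring_constant = spring_constant, tip_radius = tip_radius,
                 max_depth = max_depth, load_period = load_period),
            class = "instrument_config")
}

#' Hertz force for a spherical indenter on an elastic half-space
#'
#' \deqn{F = \tfrac{4}{3} E^* \sqrt{R}\, \delta^{3/2}} where `E*` is the
#' reduced Young's modulus, `R` the tip radius and `delta` the indentation
#' depth. Vectorized over `depth`.
#'
#' @param e_reduced Reduced Young's modulus, Pa (>= 0).
#' @param tip_radius Tip radius, m (> 0).
#' @param depth Indentation depth(s), m (>= 0).
#' @return Load(s), N.
#' @examples
#' hertz_force(1000, 4.5e-6, 2e-6)  # 8 nN
#' @export
hertz_force <- function(e_reduced, tip_radius, depth) {
  if (!is_number(e_reduced) || e_reduced < 0)
    stop_invalid_parameter("`e_reduced` must be a single nonnegative modulus in Pa")
  check_positive_scalar(tip_radius, "tip_radius")
  if (!is.numeric(depth) || any(!is.finite(depth)))
    stop_domain("`depth` must be finite numeric")
  if (any(depth < 0)) stop_domain("`depth` must be nonnegative")
  (4 / 3) * e_reduced * sqrt(tip_radius) * depth^1.5
}

#' One nanoindentation curve
#'
#' In `"reduced"` mode the samples are (scan position, load): `depth` is the
#' tip position along the indentation axis measured from the start of the
#' approach (so it includes any pre-contact travel; true indentation is
#' position minus the contact point), `load` is the force on the cell, N.
#' In `"raw"` mode the samples are (piezo displacement `z`, cantilever
#' deflection `d`), both m, and [reduce_raw()] applies the cantilever
#' mechanics F = k·d, delta = z - d.
#'
#' @param depth,load Reduced-mode samples (m, N).
#' @param z,d Raw-mode samples (m, m).
#' @param mode `"reduced"` or `"raw"`.
#' @param instrument An [instrument_config()].
#' @return Object of class `indentation_curve`.
#' @export
indentation_curve <- function(depth = NULL, load = NULL, z = NULL, d = NULL,
                              mode = c("reduced", "raw"),
                              instrument = instrument_config()) {
  mode <- match.arg(mode)
  if (!inherits(instrument, "instrument_config"))
    stop_invalid_parameter("`instrument` must be an instrument_config")
  if (mode == "reduced") {
    if (is.null(depth) || is.null(load))
      stop_domain("reduced mode needs `depth` and `load`")
    xs <- as.numeric(depth); ys <- as.numeric(load)
  } else {
    if (is.null(z) || is.null(d))
      stop_domain("raw mode needs `z` and `d`")
    xs <- as.numeric(z); ys <- as.numeric(d)
  }
  if (length(xs) != length(ys)) stop_domain("sample columns must have equal length")
  if (length(xs) < 20L)
    stop_domain("an indentation curve needs at least 20 samples")
  if (any(!is.finite(xs)) || any(!is.finite(ys)))
    stop_domain("indentation samples must be finite")
  out <- if (mode == "reduced") list(depth = xs, load = ys) else list(z = xs, d = ys)
  structure(c(out, list(mode = mode, instrument = instrument)),
            class = "indentation_curve")
}

#' @export
print.indentation_curve <- function(x, ...) {
  n <- length(if (x$mode == "reduced") x$depth else x$z)
  cat(sprintf("Indentation curve (%s mode): %d samples, tip R = %.3g um, k = %.3g N/m\n",
              x$mode, n, x$instrument$tip_radius * 1e6, x$instrument$spring_constant))
  invisible(x)
}

#' Reduce a raw cantilever recording to a load-indentation curve
#'
#' Applies F = spring_constant * d and delta = z - d. A reduced-mode input
#' is returned unchanged with a message, so the operation is idempotent.
#'
#' @param curve An [indentation_curve()].
#' @return A reduced-mode `indentation_curve` with the same sample count.
#' @export
reduce_raw <- function(curve) {
  if (!inherits(curve, "indentation_curve")) stop_domain("`curve` must be an indentation_curve")
  if (curve$mode == "reduced") {
    message("curve already in reduced mode; returning unchanged")
    return(curve)
  }
  k <- curve$instrument$spring_constant
  if (is.null(k)) stop_invalid_parameter("instrument config lacks a spring constant")
  out <- indentation_curve(depth = curve$z - curve$d, load = k * curve$d,
                           mode = "reduced", instrument = curve$instrument)
  attr(out, "ground_truth") <- attr(curve, "ground_truth")
  out
}

#' Detect the contact point of an indentation curve
#'
#' Chooses the contact sample by exhaustive piecewise model comparison:
#' for every candidate index the curve is modeled as a constant force
#' baseline before contact plus a Hertzian 3/2-power rise after it, the
#' two coefficients are solved by linear least squares, and the candidate
#' with the smallest total squared error wins (first index on ties, so the
#' result is deterministic). The winning model must beat the all-baseline
#' model by at least `min_improvement` of its squared error and carry a
#' positive Hertz coefficient; otherwise the curve is declared contact-free.
#'
#' @param curve A reduced-mode [indentation_curve()].
#' @param min_post Minimum number of post-contact samples a candidate must
#'   leave (default 5).
#' @param min_improvement Minimum fractional reduction in squared error
#'   relative to the constant-only model (default 0.2).
#'
#' @return List with `contact_index`, `contact_position` (m, scan
#'   coordinate), and `baseline_force` (N).
#' @export
detect_contact_point <- function(curve, min_post = 5L, min_improvement = 0.2) {
  if (!inherits(curve, "indentation_curve")) stop_domain("`curve` must be an indentation_curve")
  if (curve$mode != "reduced")
    stop_domain("contact detection needs a reduced-mode curve; call reduce_raw() first")
  x <- curve$depth; f <- curve$load; n <- length(x)
  rss0 <- sum((f - mean(f))^2)
  cand <- seq.int(2L, n - min_post)
  best <- list(rss = Inf, i = NA_integer_, b = NA_real_, slope = NA_real_)
  for (i in cand) {
    h <- pmax(x - x[i], 0)^1.5
    co <- stats::lm.fit(cbind(1, h), f)$coefficients
    if (!all(is.finite(co))) next
    r <- f - (co[1] + co[2] * h)
    rss <- sum(r^2)
    if (rss < best$rss) best <- list(rss = rss, i = i, b = co[1], slope = co[2])
  }
  ok <- is.finite(best$rss) && best$slope > 0 &&
    (rss0 <= 0 || (rss0 - best$rss) / rss0 > min_improvement)
  if (!ok)
    abort_cellmech("no contact point found: piecewise Hertz model does not improve on a flat baseline",
                   "cellmech_no_contact")
  list(contact_index = best$i, contact_position = x[best$i],
       baseline_force = unname(best$b))
}

#' Fit the reduced Young's modulus with the Hertz spherical model
#'
#' Least-squares fit of [hertz_force()] to the post-contact loading
#' segment, after baseline subtraction. Because the model is linear in the
#' modulus the fit is closed form: regress load on `delta^{3/2}` through
#' the origin, with `E* = 3 * slope / (4 * sqrt(R))`.
#'
#' @param curve A reduced-mode [indentation_curve()] (raw curves are
#'   reduced automatically).
#' @param depth_fraction Fit only depths up to this fraction of the maximum
#'   observed post-contact depth (default 1, the full controlled depth).
#' @param contact Optional precomputed [detect_contact_point()] result.
#'
#' @return Object of class `hertz_fit` with `e_reduced` (Pa),
#'   `contact_index`, `residual_rms` (N), `converged`, `fit_depth_range`
#'   (m, min/max depth used).
#' @examples
#' cur <- simulate_indentation(1721, noise = noise_spec(scale = 0))
#' fit_hertz(cur)$e_reduced
#' @export
fit_hertz <- function(curve, depth_fraction = 1, contact = NULL) {
  if (!inherits(curve, "indentation_curve")) stop_domain("`curve` must be an indentation_curve")
  if (curve$mode == "raw") curve <- reduce_raw(curve)
  if (!is_number(depth_fraction) || depth_fraction <= 0 || depth_fraction > 1)
    stop_invalid_parameter("`depth_fraction` must be in (0, 1]")
  if (is.null(contact)) contact <- detect_contact_point(curve)

  delta <- curve$depth - contact$contact_position
  post <- which(delta > 0)
  dmax <- max(delta[post])
  use <- post[delta[post] <= depth_fraction * dmax]
  if (length(use) < 5L)
    abort_cellmech("fewer than 5 post-contact samples in the fit range",
                   "cellmech_insufficient_data")
  y <- curve$load[use] - contact$baseline_force
  x32 <- delta[use]^1.5
  slope <- sum(x32 * y) / sum(x32^2)
  e_reduced <- 3 * slope / (4 * sqrt(curve$instrument$tip_radius))
  resid <- y - slope * x32
  structure(list(e_reduced = e_reduced,
                 contact_index = contact$contact_index,
                 baseline_force = contact$baseline_force,
                 residual_rms = sqrt(mean(resid^2)),
                 converged = is.finite(e_reduced) && e_reduced > 0,
                 fit_depth_range = range(delta[use]),
                 n_fit = length(use)),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("Hertz fit: E* = %.5g Pa over depth [%.3g, %.3g] um (%d pts)%s\n",
              x$e_reduced, x$fit_depth_range[1] * 1e6, x$fit_depth_range[2] * 1e6,
              x$n_fit, if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Convert a reduced modulus to Young's modulus
#'
#' For a rigid indenter on an incompressible-ish soft material,
#' `E = e_reduced * (1 - nu^2)`. Reported "Young's moduli" from cell
#' indentation are often the reduced modulus unconverted; this helper makes
#' the conversion explicit.
#'
#' @param e_reduced Reduced modulus, Pa.
#' @param nu Poisson ratio of the sample (default 0.5, incompressible cell).
#' @return Young's modulus, Pa.
#' @export
young_from_reduced <- function(e_reduced, nu = 0.5) {
  if (!is.numeric(e_reduced) || any(e_reduced < 0, na.rm = TRUE))
    stop_domain("`e_reduced` must be nonnegative")
  if (!is_number(nu) || nu < 0 || nu >= 1)
    stop_invalid_parameter("`nu` must be in [0, 1)")
  e_reduced * (1 - nu^2)
}

#' Summarize fitted moduli per experimental group
#'
#' Pools converged [fit_hertz()] results per group the way cell-stiffness
#' studies report them: per-group n, mean and SEM over single measurements.
#' Non-converged fits are excluded and counted. Groups keep their order of
#' first appearance; an empty group yields a row of NAs, not an error.
#'
#' @param fits List of `hertz_fit` objects (or a numeric vector of moduli).
#' @param group_labels Vector of group labels, one per fit.
#' @return `data.frame` with columns `group`, `n`, `n_excluded`, `mean_pa`,
#'   `sem_pa` (`sem_pa` is NA for n < 2).
#' @export
aggregate_moduli <- function(fits, group_labels) {
  if (is.list(fits)) {
    conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
    vals <- vapply(fits, function(f) f$e_reduced %||% NA_real_, numeric(1))
  } else {
    vals <- as.numeric(fits)
    conv <- is.finite(vals)
  }
  if (length(vals) != length(group_labels))
    stop_domain("`group_labels` must have one label per fit")
  groups <- unique(as.character(group_labels))
  rows <- lapply(groups, function(g) {
    sel <- as.character(group_labels) == g
    v <- vals[sel & conv]
    data.frame(group = g, n = length(v), n_excluded = sum(sel) - length(v),
               mean_pa = if (length(v)) mean(v) else NA_real_,
               sem_pa = if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
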