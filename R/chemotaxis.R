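#' One cell trajectory from a horizontal chemotaxis chamber
#'
#' Timestamped planar positions of a tracked cell, with a declared gradient
#' axis pointing toward the chemoattractant source (default +x, the usual
#' channel convention). Times are in minutes and positions in micrometers,
#' matching tracking-tool exports (typical frame interval 3 min over 1-6 h).
#'
#' @param cell_id Label for the cell.
#' @param times Observation times, min; strictly increasing, >= 2 samples.
#' @param xs,ys Positions, um; same length as `times`.
#' @param gradient_axis Length-2 direction toward the source; normalized
#'   internally. Default `c(1, 0)`.
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(cell_id, times, xs, ys, gradient_axis = c(1, 0)) {
  if (!is.numeric(times) || length(times) < 2L)
    abort_cellmech("a trajectory needs at least 2 timestamped positions",
                   "cellmech_invalid_trajectory")
  if (length(xs) != length(times) || length(ys) != length(times))
    abort_cellmech("`xs` and `ys` must match `times` in length",
                   "cellmech_invalid_trajectory")
  if (any(!is.finite(times)) || any(!is.finite(xs)) || any(!is.finite(ys)))
    abort_cellmech("trajectory samples must be finite", "cellmech_invalid_trajectory")
  if (any(diff(times) <= 0))
    abort_cellmech("duplicate or decreasing timestamps in trajectory",
                   "cellmech_invalid_trajectory")
  if (length(gradient_axis) != 2L || !is.numeric(gradient_axis) ||
      sum(gradient_axis^2) == 0)
    stop_invalid_parameter("`gradient_axis` must be a nonzero length-2 direction")
  g <- gradient_axis / sqrt(sum(gradient_axis^2))
  structure(list(cell_id = as.character(cell_id)[1], times = as.numeric(times),
                 xs = as.numeric(xs), ys = as.numeric(ys), gradient_axis = g),
            class = "trajectory")
}

#' Per-track chemotaxis metrics
#'
#' Computes the standard motility read-outs of a tracked cell:
#' * `path_length`: sum of step Euclidean norms, um;
#' * `velocity`: curvilinear speed, path length over elapsed time, um/min;
#' * `net_displacement`: straight-line start-to-end distance, um;
#' * `directionality`: signed chemotactic index, the projection of the net
#'   displacement onto the gradient axis divided by the path length, in
#'   \[-1, 1\]. A cell moving straight at the source scores 1, straight away
#'   -1; a closed loop scores 0. A stationary cell scores 0 velocity and,
#'   by convention, 0 directionality.
#'
#' The alternative forward-migration index per unit time (net displacement
#' along the axis / elapsed time, um/min) is returned as `fmi_velocity`.
#'
#' @param traj A [trajectory()].
#' @return Named list of metrics (class `chemotaxis_metrics`).
#' @export
track_metrics <- function(traj) {
  if (!inherits(traj, "trajectory")) stop_domain("`traj` must be a trajectory")
  dx <- diff(traj$xs); dy <- diff(traj$ys)
  path <- sum(sqrt(dx^2 + dy^2))
  elapsed <- traj$times[length(traj$times)] - traj$times[1]
  net_vec <- c(traj$xs[length(traj$xs)] - traj$xs[1],
               traj$ys[length(traj$ys)] - traj$ys[1])
  net <- sqrt(sum(net_vec^2))
  along <- sum(net_vec * traj$gradient_axis)
  structure(list(cell_id = traj$cell_id,
                 velocity = path / elapsed,
                 directionality = if (path > 0) along / path else 0,
                 path_length = path,
                 net_displacement = net,
                 fmi_velocity = along / elapsed,
                 n_frames = length(traj$times)),
            class = "chemotaxis_metrics")
}

#' Cohort summary of chemotaxis metrics
#'
#' Per-group aggregation of [track_metrics()] the way chemotaxis panels
#' report them: each dot is a cell; the table carries per-group n, mean and
#' SEM of velocity and directionality. Tracks shorter than `min_frames`
#' frames are excluded (counted, not silently dropped) because their
#' metrics are unstable. Groups appear in order of first appearance and the
#' result does not depend on input order within groups.
#'
#' @param trajs List of [trajectory()] objects.
#' @param group_labels One label per trajectory.
#' @param min_frames Minimum frames for inclusion (default 5).
#' @return `data.frame` with columns `group`, `n`, `n_excluded`,
#'   `mean_velocity`, `sem_velocity`, `mean_directionality`,
#'   `sem_directionality`.
#' @export
cohort_summary <- function(trajs, group_labels, min_frames = 5L) {
  if (length(trajs) != length(group_labels))
    stop_domain("`group_labels` must have one label per trajectory")
  mets <- lapply(trajs, track_metrics)
  nf <- vapply(mets, function(m) m$n_frames, numeric(1))
  keep <- nf >= min_frames
  groups <- unique(as.character(group_labels))
  sem <- function(v) if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_
  rows <- lapply(groups, function(g) {
    sel <- as.character(group_labels) == g
    use <- which(sel & keep)
    v <- vapply(mets[use], `[[`, numeric(1), "velocity")
    d <- vapply(mets[use], `[[`, numeric(1), "directionality")
    data.frame(group = g, n = length(use), n_excluded = sum(sel) - length(use),
               mean_velocity = if (length(v)) mean(v) else NA_real_,
               sem_velocity = sem(v),
               mean_directionality = if (length(d)) mean(d) else NA_real_,
               sem_directionality = sem(d),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Translate trajectories to a common origin
#'
#' Anchors every track's first point at (0, 0) for rose/spider plots.
#' Pure translation: step vectors, path lengths and all pairwise distances
#' are preserved, and the operation is idempotent.
#'
#' @param trajs A [trajectory()] or list of them.
#' @return Same shape as the input, recentered.
#' @export
recenter <- function(trajs) {
  one <- function(tr) {
    trajectory(tr$cell_id, tr$times, tr$xs - tr$xs[1], tr$ys - tr$ys[1],
               tr$gradient_axis)
  }
  if (inherits(trajs, "trajectory")) return(one(trajs))
  lapply(trajs, one)
}

#' Wound-area time series
#'
#' @param days Observation days, starting at 0, increasing.
#' @param areas Wound areas, mm^2; `areas[1]` (day 0) must be > 0, the rest
#'   >= 0.
#' @return Object of class `wound_series`.
#' @export
wound_series <- function(days, areas) {
  if (!is.numeric(days) || !is.numeric(areas) || length(days) != length(areas))
    stop_domain("`days` and `areas` must be numeric vectors of equal length")
  if (length(days) < 1L || days[1] != 0)
    stop_domain("a wound series must start at day 0")
  if (any(diff(days) <= 0)) stop_domain("`days` must be strictly increasing")
  if (any(areas < 0)) stop_domain("wound areas must be nonnegative")
  if (areas[1] <= 0) stop_domain("day-0 wound area must be positive")
  structure(list(days = as.numeric(days), areas = as.numeric(areas)),
            class = "wound_series")
}

#' Wound closure as percent of the initial area
#'
#' Planimetric closure: each area expressed as a percentage of the day-0
#' area, so the series starts at exactly 100 and reaches 0 at full closure.
#'
#' @param series A [wound_series()].
#' @return `data.frame` with columns `day` and `closure_pct`.
#' @examples
#' wound_closure(wound_series(c(0, 3, 6), c(78.5, 39.25, 10)))
#' @export
wound_closure <- function(series) {
  if (!inherits(series, "wound_series")) stop_domain("`series` must be a wound_series")
  data.frame(day = series$days, closure_pct = 100 * series$areas / series$areas[1])
}
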