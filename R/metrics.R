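#' Circularity index
#'
#' `4 * pi * area / perimeter^2`: 1 for a circle, smaller for ruffled
#' outlines. Used as the global ruffling readout of a cell.
#'
#' @param poly a [boundary_polygon()] (or n x 2 matrix).
#' @return dimensionless value in (0, 1] (up to polygon sampling).
#' @examples
#' circularity(boundary_polygon(rbind(c(0,0), c(1,0), c(1,1), c(0,1))))  # pi/4
#' @export
circularity <- function(poly) {
  pm <- polygon_measures(poly)
  if (pm$perimeter <= 0) stop("zero perimeter")
  4 * pi * pm$area / pm$perimeter^2
}

#' Apical/basal/height geometry of one cell
#'
#' @param S_apical apical area (um^2), > 0.
#' @param S_basal basal area (um^2), > 0.
#' @param H cell height (um), > 0.
#' @export
cell_geometry3d <- function(S_apical, S_basal, H) {
  if (any(c(S_apical, S_basal, H) <= 0))
    stop("S_apical, S_basal and H must be positive")
  structure(list(S_apical = S_apical, S_basal = S_basal, H = H),
            class = "cell_geometry3d")
}

#' Cell volume from the truncated-cone (frustum) formula
#'
#' `H * (S_apical + sqrt(S_apical * S_basal) + S_basal) / 3`.
#'
#' @param g a [cell_geometry3d()].
#' @return volume in um^3.
#' @export
cell_volume <- function(g) {
  stopifnot(inherits(g, "cell_geometry3d"))
  g$H * (g$S_apical + sqrt(g$S_apical * g$S_basal) + g$S_basal) / 3
}

#' Flatten ratio
#'
#' `sqrt(S_apical + S_basal) / H`; larger for flatter cells.
#'
#' @param g a [cell_geometry3d()].
#' @return dimensionless ratio.
#' @export
flatten_ratio <- function(g) {
  stopifnot(inherits(g, "cell_geometry3d"))
  if (g$H == 0) stop("zero height")
  sqrt(g$S_apical + g$S_basal) / g$H
}

#' Uniformly sampled scalar time series
#'
#' @param values numeric vector (>= 2 finite values).
#' @param dt_sample sampling interval in minutes.
#' @param label series label.
#' @export
signal_trace <- function(values, dt_sample, label = "signal") {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("a signal trace needs >= 2 points")
  if (any(!is.finite(values))) stop("trace values must be finite")
  if (dt_sample <= 0) stop("dt_sample must be positive")
  structure(list(values = values, dt_sample = dt_sample, label = label),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %s: %d samples at %g min\n",
              x$label, length(x$values), x$dt_sample))
  invisible(x)
}

trace_times <- function(tr) (seq_along(tr$values) - 1) * tr$dt_sample

#' Detect de novo membrane ruffles along a boundary trajectory
#'
#' A ruffle is a maximal contiguous boundary arc whose signed curvature
#' exceeds `curvature_threshold` over at least `min_arc_len` vertices and
#' that was absent in the previous frame (no overlapping above-threshold
#' arc at the same vertex indices). Frames must share vertex sampling.
#' Each event carries the orientation of the outward normal at the arc
#' midpoint, measured counter-clockwise from the A-P axis in [0, 360).
#'
#' @param traj list of [boundary_polygon()] frames of one cell (>= 2),
#'   time-ordered, equal vertex counts.
#' @param curvature_threshold 1/um; default `2 / equivdiameter` of each
#'   frame (twice the equivalent-circle curvature).
#' @param min_arc_len minimum arc length in vertices.
#' @param axis an [axis_frame()].
#' @param smooth_window passed to [discrete_curvature()].
#' @return data.frame of events: `frame_time`, `arc_start`, `arc_end`
#'   (vertex indices, inclusive; may wrap), `orientation_deg`.
#' @export
detect_ruffles <- function(traj, curvature_threshold = NULL, min_arc_len = 3L,
                           axis = axis_frame(), smooth_window = 3L) {
  if (length(traj) < 2L) stop("need at least 2 frames")
  n <- nrow(as_poly_matrix(traj[[1]]))
  above <- lapply(traj, function(p) {
    pm <- as_poly_matrix(p)
    if (nrow(pm) != n) stop("all frames must share vertex sampling")
    thr <- if (is.null(curvature_threshold))
      2 / polygon_measures(pm)$equivdiameter else curvature_threshold
    discrete_curvature(boundary_polygon(pm), smooth_window) > thr
  })
  events <- list()
  for (fi in 2:length(traj)) {
    arcs <- circular_runs(above[[fi]], min_arc_len)
    prev <- above[[fi - 1]]
    for (arc in arcs) {
      if (any(prev[arc$idx])) next  # not de novo
      mid <- arc$idx[ceiling(length(arc$idx) / 2)]
      nor <- outward_normal(traj[[fi]], mid)
      ang <- atan2(sum(nor * axis$dv_unit), sum(nor * axis$ap_unit)) * 180 / pi
      events[[length(events) + 1L]] <- data.frame(
        frame_time = attr(traj[[fi]], "frame_time"),
        arc_start = arc$idx[1], arc_end = arc$idx[length(arc$idx)],
        orientation_deg = (ang + 360) %% 360)
    }
  }
  if (!length(events))
    return(data.frame(frame_time = numeric(0), arc_start = integer(0),
                      arc_end = integer(0), orientation_deg = numeric(0)))
  do.call(rbind, events)
}

# maximal circular TRUE runs of length >= min_len, as index vectors
circular_runs <- function(flag, min_len = 1L) {
  n <- length(flag)
  if (!any(flag)) return(list())
  if (all(flag)) return(list(list(idx = seq_len(n))))
  s <- which(!flag)[1]
  rot <- ((seq_len(n) + s - 2L) %% n) + 1L   # rotated index -> original index
  f <- flag[rot]
  r <- rle(f)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (j in seq_along(r$values)) {
    if (r$values[j] && r$lengths[j] >= min_len)
      out[[length(out) + 1L]] <- list(idx = rot[starts[j]:ends[j]])
  }
  out
}

#' 12-bin rose diagram of ruffle orientations
#'
#' Counts ruffle events per 30-degree sector, half-open bins
#' `[k*30, (k+1)*30)` relative to the A-P axis.
#'
#' @param events data.frame from [detect_ruffles()] (needs
#'   `orientation_deg`), or a numeric vector of orientations in degrees.
#' @return integer vector of 12 counts, named by bin start angle.
#' @export
ruffle_rose <- function(events) {
  ang <- if (is.data.frame(events)) events$orientation_deg else as.numeric(events)
  if (any(ang < 0 | ang >= 360)) stop("orientations must be in [0, 360)")
  bins <- floor(ang / 30) + 1L
  counts <- tabulate(bins, nbins = 12L)
  names(counts) <- paste0(seq(0, 330, by = 30))
  counts
}

#' Migration distance and per-axis velocities
#'
#' Distance is the total displacement (straight line between first and last
#' centroid); velocities are per-axis displacement divided by elapsed time.
#'
#' @param centroids n x 2 matrix of centroid positions (um), time-ordered.
#' @param times length-n vector of frame times (min).
#' @param axis an [axis_frame()].
#' @return list `distance` (um), `v_ap`, `v_dv` (um/min; positive along the
#'   A->P and D->V unit vectors respectively).
#' @export
migration_kinematics <- function(centroids, times, axis = axis_frame()) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 2L) stop("need >= 2 frames")
  elapsed <- times[length(times)] - times[1]
  if (elapsed == 0) stop("zero elapsed time")
  d <- centroids[nrow(centroids), ] - centroids[1, ]
  list(distance = sqrt(sum(d^2)),
       v_ap = sum(d * axis$ap_unit) / elapsed,
       v_dv = sum(d * axis$dv_unit) / elapsed)
}

#' Oscillation period by autocorrelation
#'
#' Lag of the first autocorrelation maximum after the zero-lag peak, in
#' minutes. The trace is mean-removed; the search is bounded to lags in
#' `[2 * dt_sample, length/2]`. Returns `NA` with a message when no
#' secondary maximum exists (aperiodic or constant trace).
#'
#' @param trace a [signal_trace()].
#' @return period in minutes, or `NA_real_` if no period is detected.
#' @export
autocorr_period <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"))
  x <- trace$values - mean(trace$values)
  n <- length(x)
  if (stats::var(x) == 0) { message("no period detected"); return(NA_real_) }
  max_lag <- floor(n / 2)
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  # local maxima over lags >= 2 samples
  lag_idx <- 2:(max_lag - 1)
  is_max <- ac[lag_idx + 1] > ac[lag_idx] & ac[lag_idx + 1] >= ac[lag_idx + 2]
  cand <- lag_idx[is_max] + 0  # lag in samples (ac index i+1 <-> lag i)
  if (!length(cand)) { message("no period detected"); return(NA_real_) }
  cand[1] * trace$dt_sample
}

#' Photobleaching correction
#'
#' If the background never drops by 5% or more between adjacent frames, the
#' trace is returned unchanged (no significant bleaching). Otherwise a
#' single-exponential decay is fitted to the background and the trace is
#' divided by the fitted decay normalized to its first frame.
#'
#' @param trace,background [signal_trace()] objects of equal length and
#'   sampling; background must be strictly positive.
#' @param trigger maximum tolerated adjacent-frame fractional drop
#'   (default 0.05).
#' @return corrected [signal_trace()].
#' @export
bleach_correct <- function(trace, background, trigger = 0.05) {
  stopifnot(inherits(trace, "signal_trace"), inherits(background, "signal_trace"))
  b <- background$values
  if (length(b) != length(trace$values)) stop("trace and background lengths differ")
  if (any(b <= 0)) stop("background must be strictly positive")
  drops <- (b[-length(b)] - b[-1]) / b[-length(b)]
  if (max(drops) < trigger) return(trace)
  tt <- trace_times(background)
  fit <- stats::lm(log(b) ~ tt)
  decay <- exp(stats::fitted(fit))
  decay <- decay / decay[1]
  signal_trace(trace$values / decay, trace$dt_sample,
               label = paste0(trace$label, "_bleachcorr"))
}

#' Phase boundaries from a circularity trace
#'
#' Operationalizes the phase sequence on a tissue-mean circularity trace.
#' The increasing onset is the change-point where the smoothed slope turns
#' from non-positive into its longest sustained positive run (the sharp
#' circularity recovery); the ruffling onset is the start of the longest
#' sustained decline preceding that recovery. Both are slope-sign based, so
#' the result is invariant to uniform scaling of the trace. Because a
#' centred moving average advances the apparent start of a sharp transition
#' by half the window, the reported onsets are compensated by
#' `(smooth_window - 1) / 2` samples.
#'
#' @param trace a [signal_trace()] of circularity (or any shape index).
#' @param smooth_window odd moving-average window in samples (default 9).
#' @return list `ruffling_onset`, `increasing_onset` in minutes
#'   (`NA` with a message when a transition is absent, e.g. monotone trace).
#' @export
phase_segment <- function(trace, smooth_window = 9L) {
  stopifnot(inherits(trace, "signal_trace"))
  x <- trace$values
  n <- length(x)
  w <- min(smooth_window, if (n %% 2L == 1L) n else n - 1L)
  if (w >= 3L) x <- stats::filter(x, rep(1 / w, w), sides = 2)
  x <- as.numeric(x)
  ok <- !is.na(x)
  off <- which(ok)[1] - 1L
  x <- x[ok]
  slope <- diff(x)
  r <- rle(slope < 0)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  neg <- which(r$values)
  if (!length(neg)) {
    message("no transition found")
    return(list(ruffling_onset = NA_real_, increasing_onset = NA_real_))
  }
  # recovery = longest positive run that follows at least one decline
  pos <- which(!r$values & starts > starts[neg[1]])
  inc_i <- NA_integer_
  if (length(pos)) inc_i <- starts[pos[which.max(r$lengths[pos])]]
  # ruffling = longest decline before the recovery (or overall if none)
  neg_before <- if (is.na(inc_i)) neg else neg[starts[neg] < inc_i]
  ruf_i <- starts[neg_before[which.max(r$lengths[neg_before])]]
  dt <- trace$dt_sample
  comp <- (w - 1L) %/% 2L   # smoothing-advance compensation
  n_out <- length(trace$values)
  to_min <- function(i) min(i - 1L + off + comp, n_out - 1L) * dt
  list(ruffling_onset = to_min(ruf_i),
       increasing_onset = if (is.na(inc_i)) NA_real_ else to_min(inc_i))
}
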