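# Seeded generators emulating the statistical structure of the imaging
# data: ruffled boundaries, pulsatile signal cascades, shifted two-channel
# images, bleached traces and oriented fiber textures. Every generator is
# deterministic given its seed and returns its ground truth alongside the
# data so downstream estimators can be tested by round-trip recovery.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
      else assign(".Random.seed", old, .GlobalEnv)
    })
    set.seed(seed)
  }
  force(code)
}

#' Ruffled test polygon (rose curve)
#'
#' `r(theta) = base_radius * (1 + amplitude * cos(n_lobes * theta))`,
#' sampled at `n_points`; `n_lobes = 0` gives a circle. Optional phase
#' jitter is seeded.
#'
#' @param base_radius um.
#' @param n_lobes number of outward lobes (>= 0).
#' @param amplitude relative lobe amplitude, `< 1` (so the radius stays
#'   positive).
#' @param n_points boundary samples (>= 8).
#' @param seed seed for the random phase; `NULL` = phase 0.
#' @param frame_time,cell_id forwarded to [boundary_polygon()].
#' @return a [boundary_polygon()] with attribute `ground_truth`
#'   (list: n_lobes, amplitude, phase).
#' @export
make_ruffled_polygon <- function(base_radius = 5, n_lobes = 5, amplitude = 0.2,
                                 n_points = 200, seed = NULL,
                                 frame_time = 0, cell_id = "synthetic") {
  if (n_lobes < 0) stop("n_lobes must be >= 0")
  if (amplitude >= 1 || amplitude < 0) stop("amplitude must be in [0, 1)")
  if (n_points < 8) stop("n_points must be >= 8")
  phase <- if (is.null(seed)) 0 else with_seed(seed, stats::runif(1, 0, 2 * pi))
  th <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  r <- base_radius * (1 + amplitude * cos(n_lobes * (th - phase)))
  poly <- boundary_polygon(cbind(r * cos(th), r * sin(th)),
                           frame_time = frame_time, cell_id = cell_id)
  attr(poly, "ground_truth") <- list(n_lobes = n_lobes, amplitude = amplitude,
                                     phase = phase)
  poly
}

#' Specification of a pulsatile signal cascade
#'
#' Describes the multichannel pulse trains used to emulate the measured
#' temporal cascade (Rac1 activity -> ruffle-associated area increase ->
#' Rho1 activity -> basal actomyosin -> focal adhesions): one shared
#' period, cumulative inter-channel lags, additive Gaussian noise.
#' Default lags follow the measured orderings (Rac leads area by ~3 min,
#' Rho follows area by ~1 min, actomyosin 2 min after Rho, adhesions 1 min
#' later); the default period of 8 min sits in the observed 5-10 min band.
#'
#' @param period pulse period (min), > 0.
#' @param labels channel names (first channel leads).
#' @param lags pairwise lags in minutes, `length(labels) - 1` values, each
#'   `|lag| < period / 2`.
#' @param noise_sd Gaussian noise sd as a fraction of pulse amplitude.
#' @param duration total duration (min).
#' @param dt_sample sampling interval (min), `<= min(lags)`.
#' @param seed integer seed, recorded.
#' @export
cascade_spec <- function(period = 8,
                         labels = c("Rac", "area", "Rho", "actomyosin", "adhesion"),
                         lags = c(3, 1, 2, 1),
                         noise_sd = 0.05, duration = 40, dt_sample = 0.5,
                         seed = 1L) {
  if (period <= 0) stop("period must be positive")
  if (length(lags) != length(labels) - 1L)
    stop("need one lag per adjacent channel pair")
  if (any(abs(lags) >= period / 2)) stop("|lags| must be < period/2")
  if (dt_sample > min(abs(lags))) stop("dt_sample must be <= the smallest lag")
  structure(list(period = period, labels = labels, lags = lags,
                 noise_sd = noise_sd, duration = duration,
                 dt_sample = dt_sample, seed = seed),
            class = "cascade_spec")
}

#' Generate a pulsatile signal cascade
#'
#' Each channel is a raised-cosine pulse train (pulse width = period / 2)
#' with the shared period, phase-delayed by the cumulative lags, plus
#' Gaussian noise. Ground-truth lags are returned alongside.
#'
#' @param spec a [cascade_spec()].
#' @return list: `traces` (named list of [signal_trace()]), `ground_truth`
#'   (list with `lags`, `period`, `seed`).
#' @export
make_pulse_cascade <- function(spec = cascade_spec()) {
  stopifnot(inherits(spec, "cascade_spec"))
  tt <- seq(0, spec$duration, by = spec$dt_sample)
  offsets <- c(0, cumsum(spec$lags))
  traces <- with_seed(spec$seed, {
    lapply(seq_along(spec$labels), function(i) {
      tau <- (tt - offsets[i]) %% spec$period
      # raised-cosine pulse occupying the first half of each period
      v <- ifelse(tau < spec$period / 2,
                  0.5 * (1 - cos(2 * pi * tau / (spec$period / 2))), 0)
      v <- v + stats::rnorm(length(v), sd = spec$noise_sd)
      signal_trace(v, spec$dt_sample, label = spec$labels[i])
    })
  })
  names(traces) <- spec$labels
  list(traces = traces,
       ground_truth = list(lags = stats::setNames(spec$lags,
                             paste(spec$labels[-length(spec$labels)],
                                   spec$labels[-1], sep = "_to_")),
                           period = spec$period, seed = spec$seed))
}

#' Two-channel image pair with a known spatial shift
#'
#' Channel 1 is a field of random Gaussian blobs; channel 2 is channel 1
#' translated by `shift` pixels along x plus independent Gaussian noise.
#'
#' @param size image side in px.
#' @param blob_density expected blobs per 1000 px^2.
#' @param shift integer x-shift of channel 2 in px, `|shift| < size/4`.
#' @param noise_sd additive noise sd (fraction of blob peak).
#' @param seed integer seed.
#' @param pixel_size nm per px.
#' @return an [image_pair()] with attribute `ground_truth`
#'   (list: shift_px, shift_nm).
#' @export
make_shifted_image_pair <- function(size = 64, blob_density = 8, shift = 4,
                                    noise_sd = 0.02, seed = 1L,
                                    pixel_size = 100) {
  if (abs(shift) >= size / 4) stop("|shift| must be < size/4")
  with_seed(seed, {
    n_blob <- max(3L, stats::rpois(1, blob_density * size^2 / 1000))
    cx <- stats::runif(n_blob, 1, size)
    cy <- stats::runif(n_blob, 1, size)
    sg <- stats::runif(n_blob, 1.5, 3)
    amp <- stats::runif(n_blob, 0.5, 1)
    xs <- matrix(seq_len(size), size, size, byrow = TRUE)  # columns = x
    ys <- matrix(seq_len(size), size, size)                # rows = y
    ch1 <- Reduce(`+`, lapply(seq_len(n_blob), function(b)
      amp[b] * exp(-((xs - cx[b])^2 + (ys - cy[b])^2) / (2 * sg[b]^2))))
    ch2 <- Reduce(`+`, lapply(seq_len(n_blob), function(b)
      amp[b] * exp(-((xs - cx[b] - shift)^2 + (ys - cy[b])^2) / (2 * sg[b]^2))))
    if (noise_sd > 0)
      ch2 <- ch2 + matrix(stats::rnorm(size^2, sd = noise_sd), size)
    ch2 <- pmax(ch2, 0)
    pair <- image_pair(ch1, ch2, pixel_size = pixel_size)
    attr(pair, "ground_truth") <- list(shift_px = shift,
                                       shift_nm = shift * pixel_size)
    pair
  })
}

#' Photobleached trace with matching background
#'
#' `observed = base * exp(-decay_rate * t)` (plus optional noise);
#' `background = constant * exp(-decay_rate * t)`.
#'
#' @param base_trace a [signal_trace()] of the true signal.
#' @param decay_rate bleaching rate per minute (>= 0).
#' @param noise_sd additive noise on the observed trace.
#' @param background_level constant pre-bleach background intensity.
#' @param seed integer seed.
#' @return list: `observed`, `background` ([signal_trace()]s),
#'   `ground_truth` (decay_rate).
#' @export
make_bleached_trace <- function(base_trace, decay_rate = 0.02, noise_sd = 0,
                                background_level = 100, seed = 1L) {
  stopifnot(inherits(base_trace, "signal_trace"))
  if (decay_rate < 0) stop("decay_rate must be >= 0")
  tt <- trace_times(base_trace)
  decay <- exp(-decay_rate * tt)
  obs <- base_trace$values * decay
  if (noise_sd > 0)
    obs <- obs + with_seed(seed, stats::rnorm(length(obs), sd = noise_sd))
  list(observed = signal_trace(obs, base_trace$dt_sample,
                               label = paste0(base_trace$label, "_bleached")),
       background = signal_trace(background_level * decay,
                                 base_trace$dt_sample, label = "background"),
       ground_truth = list(decay_rate = decay_rate))
}

#' Fiber-texture image with known orientations
#'
#' Draws anti-aliased straight segments at the requested angles (degrees
#' CCW from the A-P/x axis) in the given proportions, plus Gaussian noise.
#'
#' @param size image side in px.
#' @param orientation_mix named numeric vector: `c("90" = 0.7, "0" = 0.3)`;
#'   weights must sum to 1.
#' @param n_lines total number of segments.
#' @param line_width Gaussian cross-section sd of a segment in px.
#' @param noise_sd additive noise sd.
#' @param seed integer seed.
#' @return numeric matrix with attribute `ground_truth`
#'   (the orientation mix).
#' @export
make_fiber_image <- function(size = 64, orientation_mix = c("90" = 1),
                             n_lines = 20, line_width = 1, noise_sd = 0.02,
                             seed = 1L) {
  w <- as.numeric(orientation_mix)
  if (abs(sum(w) - 1) > 1e-9) stop("orientation weights must sum to 1")
  angles <- as.numeric(names(orientation_mix))
  counts <- round(w * n_lines)
  with_seed(seed, {
    img <- matrix(0, size, size)
    xs <- matrix(seq_len(size), size, size, byrow = TRUE)
    ys <- matrix(seq_len(size), size, size)
    for (j in seq_along(angles)) {
      th <- angles[j] * pi / 180
      u <- c(cos(th), sin(th))            # along the line
      for (k in seq_len(counts[j])) {
        p0 <- stats::runif(2, 1, size)    # a point on the line
        # perpendicular distance of every pixel to the infinite line
        d <- (xs - p0[1]) * (-u[2]) + (ys - p0[2]) * u[1]
        # longitudinal window so segments have finite length
        s <- (xs - p0[1]) * u[1] + (ys - p0[2]) * u[2]
        seg <- exp(-d^2 / (2 * line_width^2)) * (abs(s) < size / 3)
        img <- img + seg
      }
    }
    if (noise_sd > 0) img <- img + matrix(stats::rnorm(size^2, sd = noise_sd), size)
    img <- pmax(img, 0)
    attr(img, "ground_truth") <- list(orientation_mix = orientation_mix)
    img
  })
}
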