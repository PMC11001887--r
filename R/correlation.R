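#' Two-channel image pair
#'
#' Equal-shape 2-D intensity arrays from two cameras/channels, with the
#' pixel size in nanometres. Images are plain numeric matrices (rows = y,
#' columns = x).
#'
#' @param channel1,channel2 numeric matrices of identical dimensions,
#'   finite and non-negative.
#' @param pixel_size nm per pixel.
#' @export
image_pair <- function(channel1, channel2, pixel_size = 100) {
  channel1 <- as.matrix(channel1); channel2 <- as.matrix(channel2)
  if (!identical(dim(channel1), dim(channel2)))
    stop("channels must have identical shapes")
  if (any(!is.finite(channel1)) || any(!is.finite(channel2)))
    stop("intensities must be finite")
  if (any(channel1 < 0) || any(channel2 < 0))
    stop("intensities must be non-negative")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  structure(list(channel1 = channel1, channel2 = channel2,
                 pixel_size = pixel_size), class = "image_pair")
}

#' Masked Pearson colocalization coefficient
#'
#' Pearson coefficient over the pixels whose intensity exceeds the
#' `low_fraction` quantile in *both* channels (the low-intensity rejection
#' used before computing the cross-correlation function). The denominator
#' is the standard Pearson `sqrt(sum(d1^2) * sum(d2^2))`.
#'
#' @param pair an [image_pair()], or `channel2` given separately.
#' @param low_fraction fraction of low-intensity pixels rejected per
#'   channel, in [0, 1); default 0.10.
#' @return Pearson coefficient in [-1, 1].
#' @export
masked_pearson <- function(pair, low_fraction = 0.10) {
  stopifnot(inherits(pair, "image_pair"))
  if (low_fraction < 0 || low_fraction >= 1)
    stop("low_fraction must be in [0, 1)")
  i1 <- pair$channel1; i2 <- pair$channel2
  mask <- i1 > stats::quantile(i1, low_fraction) &
          i2 > stats::quantile(i2, low_fraction)
  masked_pearson_raw(i1[mask], i2[mask])
}

masked_pearson_raw <- function(x, y) {
  if (length(x) < 2L) stop("mask of < 2 pixels")
  d1 <- x - mean(x); d2 <- y - mean(y)
  den <- sqrt(sum(d1^2) * sum(d2^2))
  if (den == 0) stop("zero variance inside the mask")
  sum(d1 * d2) / den
}

#' Van Steensel cross-correlation function (spatial CCF)
#'
#' Pearson coefficient after translating channel 2 over a range of integer
#' x-shifts (no rotation), restricted to the overlap region and to the
#' joint above-threshold mask. The shift envelope defaults to 940 nm,
#' converted to pixels by `pixel_size` (rounded down). Sign convention:
#' `peak_shift` equals the displacement of channel-2 content relative to
#' channel 1 -- an image pair whose second channel is the first translated
#' by +4 px peaks at +4 px.
#'
#' @param pair an [image_pair()].
#' @param max_shift_nm shift envelope in nm (default 940).
#' @param low_fraction per-channel low-intensity rejection (default 0.10).
#' @return a `ccf_curve` data.frame with columns `shift_px`, `shift_nm`,
#'   `coefficient`, plus attributes `peak_shift_px`, `peak_shift_nm`,
#'   `peak_value`.
#' @export
vsc_ccf <- function(pair, max_shift_nm = 940, low_fraction = 0.10) {
  stopifnot(inherits(pair, "image_pair"))
  w <- ncol(pair$channel1)
  max_px <- floor(max_shift_nm / pair$pixel_size)
  if (max_px > w / 2) stop("max_shift exceeds half the image width")
  shifts <- (-max_px):max_px
  coef <- vapply(shifts, function(s) {
    # columns of ch1 compared against columns of ch2 displaced by s:
    # ch2 content moved by +s matches ch1 when we read ch2 at col - s
    if (s >= 0) {
      c1 <- pair$channel1[, (1 + s):w, drop = FALSE]
      c2 <- pair$channel2[, 1:(w - s), drop = FALSE]
    } else {
      c1 <- pair$channel1[, 1:(w + s), drop = FALSE]
      c2 <- pair$channel2[, (1 - s):w, drop = FALSE]
    }
    m <- c1 > stats::quantile(pair$channel1, low_fraction) &
         c2 > stats::quantile(pair$channel2, low_fraction)
    if (sum(m) < 2L) return(NA_real_)
    tryCatch(masked_pearson_raw(c1[m], c2[m]), error = function(e) NA_real_)
  }, numeric(1))
  curve <- data.frame(shift_px = -shifts, shift_nm = -shifts * pair$pixel_size,
                      coefficient = coef)
  curve <- curve[order(curve$shift_px), ]
  rownames(curve) <- NULL
  pk <- which.max(curve$coefficient)
  structure(curve, class = c("ccf_curve", "data.frame"),
            peak_shift_px = curve$shift_px[pk],
            peak_shift_nm = curve$shift_nm[pk],
            peak_value = curve$coefficient[pk])
}

#' Min-max normalization of colocalization coefficients
#'
#' Rescales a series of coefficients to [0, 1]:
#' `(P - min(P)) / (max(P) - min(P))`; order-preserving and invariant to
#' positive affine transforms of the input.
#'
#' @param p numeric vector with at least 2 distinct values.
#' @return numeric vector in [0, 1].
#' @export
temporal_coloc_normalize <- function(p) {
  p <- as.numeric(p)
  if (length(p) < 2L) stop("need >= 2 values")
  rng <- range(p)
  if (diff(rng) == 0) stop("constant series: zero range")
  (p - rng[1]) / diff(rng)
}

#' Temporal lag between two pulsatile traces
#'
#' Lag (in minutes, positive when `b` follows `a`) maximizing the
#' normalized cross-correlation of the mean-removed traces over integer-
#' sample lags within `max_lag`.
#'
#' @param a,b [signal_trace()] objects with equal sampling.
#' @param max_lag maximum absolute lag to search (min).
#' @return lag in minutes.
#' @export
lag_estimate <- function(a, b, max_lag) {
  stopifnot(inherits(a, "signal_trace"), inherits(b, "signal_trace"))
  if (abs(a$dt_sample - b$dt_sample) > 1e-12)
    stop("traces must share the sampling interval")
  xa <- a$values - mean(a$values)
  xb <- b$values - mean(b$values)
  if (stats::var(xa) == 0 || stats::var(xb) == 0) stop("zero-variance trace")
  n <- min(length(xa), length(xb))
  xa <- xa[seq_len(n)]; xb <- xb[seq_len(n)]
  kmax <- min(floor(max_lag / a$dt_sample), n - 2L)
  lags <- (-kmax):kmax
  cc <- vapply(lags, function(k) {
    if (k >= 0) { u <- xa[1:(n - k)]; v <- xb[(1 + k):n] }
    else        { u <- xa[(1 - k):n]; v <- xb[1:(n + k)] }
    if (stats::var(u) == 0 || stats::var(v) == 0) return(-Inf)
    stats::cor(u, v)
  }, numeric(1))
  lags[which.max(cc)] * a$dt_sample
}
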