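#' Stress-fiber orientation analysis with an oriented (Gabor) filter bank
#'
#' Convolves a grayscale image with a bank of `n_orientations` evenly
#' spaced Gabor filters covering [0, 180) degrees, assigns every
#' foreground pixel the orientation of its strongest response, and returns
#' the orientation histogram together with the D-V-isolated image (the
#' response at the bank orientation closest to the D-V axis). Angles are
#' measured counter-clockwise from the A-P axis; a fiber "at 0 degrees"
#' runs along A-P, one "at 90 degrees" along D-V.
#'
#' @param image numeric matrix (rows = y, columns = x).
#' @param axis an [axis_frame()].
#' @param n_orientations number of filter orientations (default 12).
#' @param wavelength carrier wavelength of the Gabor filters in px.
#' @param sigma Gaussian envelope sd in px (elongated 2:1 along the fiber).
#' @param foreground_quantile pixels above this intensity quantile form the
#'   foreground mask.
#' @return list: `histogram` (counts named by orientation in degrees),
#'   `dominant_deg` (modal orientation), `dv_image` (response magnitude at
#'   the D-V orientation), `orientations_deg`.
#' @export
fiber_polarity <- function(image, axis = axis_frame(), n_orientations = 12L,
                           wavelength = 8, sigma = 3,
                           foreground_quantile = 0.7) {
  image <- as.matrix(image)
  angles <- seq(0, 180, length.out = n_orientations + 1L)[-(n_orientations + 1L)]
  thr <- stats::quantile(image, foreground_quantile)
  mask <- image > thr
  if (!any(mask)) stop("empty foreground mask")
  resp <- lapply(angles, function(a)
    abs(convolve2d_fft(image, gabor_kernel(a, wavelength, sigma))))
  stack <- array(unlist(resp), dim = c(dim(image), length(angles)))
  best <- apply(stack, c(1, 2), which.max)
  counts <- tabulate(best[mask], nbins = length(angles))
  names(counts) <- paste0(angles)
  dv_deg <- (atan2(axis$dv_unit[2], axis$dv_unit[1]) -
             atan2(axis$ap_unit[2], axis$ap_unit[1])) * 180 / pi
  dv_deg <- dv_deg %% 180
  dv_i <- which.min(pmin(abs(angles - dv_deg), 180 - abs(angles - dv_deg)))
  list(histogram = counts,
       dominant_deg = angles[which.max(counts)],
       dv_image = resp[[dv_i]],
       orientations_deg = angles)
}

# Gabor kernel responding to line-like structures oriented at `angle_deg`
# (degrees CCW from +x): Gaussian envelope elongated along the line, cosine
# carrier across it.
gabor_kernel <- function(angle_deg, wavelength = 8, sigma = 3, gamma = 0.5) {
  half <- ceiling(3 * sigma / gamma)
  # rows of the kernel matrix index y, columns index x (image convention)
  g <- expand.grid(y = -half:half, x = -half:half)
  th <- angle_deg * pi / 180
  # x' across the line (carrier direction), y' along it
  xr <- -g$x * sin(th) + g$y * cos(th)
  yr <-  g$x * cos(th) + g$y * sin(th)
  k <- exp(-(gamma^2 * xr^2 + yr^2) / (2 * (sigma / gamma)^2)) *
    cos(2 * pi * xr / wavelength)
  k <- k - mean(k)  # zero-DC so flat regions give no response
  matrix(k, nrow = 2 * half + 1)
}

# circular 2-D convolution via FFT, kernel centred
convolve2d_fft <- function(image, kernel) {
  nr <- nrow(image); nc <- ncol(image)
  kr <- nrow(kernel); kc <- ncol(kernel)
  if (kr > nr || kc > nc) stop("kernel larger than image")
  pad <- matrix(0, nr, nc)
  pad[1:kr, 1:kc] <- kernel
  # centre the kernel at (1,1) with wraparound
  pad <- pad[((seq_len(nr) - 1 + (kr %/% 2)) %% nr) + 1,
             ((seq_len(nc) - 1 + (kc %/% 2)) %% nc) + 1]
  Re(stats::fft(stats::fft(image) * Conj(stats::fft(pad)), inverse = TRUE)) / (nr * nc)
}
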