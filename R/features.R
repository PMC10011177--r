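# Layer I: feature extraction.
#
# An RGB image is expanded into up to 27 channels: intensity, the CIELab
# a/b color-opponency pair, 8 Gabor orientation channels on intensity
# (low level), and 8 orientation channels on each opponency channel
# (medium level: joint color x orientation selectivity, after V1 cells
# tuned to such conjunctions).

#' Intensity channel of an RGB image
#'
#' Standard luma weighting `0.2989 R + 0.5870 G + 0.1140 B` applied to RGB
#' values in `[0, 1]`.
#'
#' @param img H x W x 3 array in `[0, 1]` (see [as_rgb_image()]).
#' @return H x W numeric matrix.
#' @export
compute_intensity <- function(img) {
  img <- as_rgb_image(img)
  d <- dim(img)
  matrix(0.2989 * img[, , 1] + 0.5870 * img[, , 2] + 0.1140 * img[, , 3],
         d[1], d[2])
}

#' Color-opponency channels of an RGB image
#'
#' Converts sRGB (D65) to CIELab and returns the a channel as the
#' green-red (RG) opponency map and the b channel as the blue-yellow (BY)
#' opponency map, on the native Lab scale (roughly -100..100).
#'
#' @inheritParams compute_intensity
#' @return List with matrices `RG` and `BY`.
#' @export
compute_opponency <- function(img) {
  img <- as_rgb_image(img)
  d <- dim(img)
  rgb <- matrix(img, ncol = 3)
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  list(RG = matrix(lab[, 2], d[1], d[2]),
       BY = matrix(lab[, 3], d[1], d[2]))
}

#' Bank of oriented Gabor filters
#'
#' Real cosine-phase Gabor kernels at `n_orient` equally spaced angles
#' `k * pi / n_orient`, `k = 0 .. n_orient - 1`. The angle is the direction
#' of the carrier wave; a kernel at angle `theta` responds maximally to a
#' grating whose stripes run perpendicular to `theta`. The Gaussian
#' envelope uses `sigma = 0.56 * wavelength` (about one octave of spatial
#' frequency bandwidth) and unit aspect ratio. Each kernel has its mean
#' subtracted (zero DC response, so constant images map to zero) and is
#' scaled to unit L2 norm.
#'
#' @param wavelength Carrier wavelength in pixels (default 10).
#' @param n_orient Number of orientations (default 8).
#' @return Object of class `gabor_bank`: list with `kernels` (list of odd
#'   square matrices), `thetas`, `wavelength`.
#' @export
make_gabor_bank <- function(wavelength = 10, n_orient = 8) {
  if (!is.numeric(wavelength) || length(wavelength) != 1 || wavelength <= 0)
    stop_config("wavelength must be a positive number")
  if (!is.numeric(n_orient) || n_orient < 1 || n_orient != round(n_orient))
    stop_config("n_orient must be a positive integer")
  sigma <- 0.56 * wavelength
  half <- ceiling(3 * sigma)
  xs <- seq(-half, half)
  thetas <- (seq_len(n_orient) - 1) * pi / n_orient
  kernels <- lapply(thetas, function(th) {
    X <- matrix(xs, length(xs), length(xs), byrow = TRUE)  # column coordinate
    Y <- matrix(xs, length(xs), length(xs))                # row coordinate
    Xr <- X * cos(th) + Y * sin(th)
    Yr <- -X * sin(th) + Y * cos(th)
    k <- exp(-(Xr^2 + Yr^2) / (2 * sigma^2)) * cos(2 * pi * Xr / wavelength)
    k <- k - mean(k)
    k / sqrt(sum(k^2))
  })
  structure(list(kernels = kernels, thetas = thetas, wavelength = wavelength),
            class = "gabor_bank")
}

#' Extract the model's feature channels from an RGB image
#'
#' Low-level channels: intensity `I`, opponency `RG` and `BY`, and the 8
#' orientation channels `O<k>.I` (Gabor-filtered intensity). The full
#' configuration adds the 16 medium-level channels `O<k>.RG`, `O<k>.BY`
#' (Gabor-filtered opponency). Orientation channels keep the signed filter
#' output; absolute values are only taken later by the center-surround
#' operator. Convolution uses reflect padding to avoid artificial border
#' contrast.
#'
#' @inheritParams compute_intensity
#' @param feature_config `"full"` (27 channels) or `"low_level_only"`
#'   (11 channels).
#' @param bank Optional [make_gabor_bank()] result; defaults to the model's
#'   8-orientation, wavelength-10 bank.
#' @return Object of class `feature_stack`: list with named `channels`
#'   (list of H x W matrices) and `config`.
#' @export
extract_features <- function(img, feature_config = c("full", "low_level_only"),
                             bank = make_gabor_bank()) {
  if (!is.character(feature_config) ||
      !feature_config[1] %in% c("full", "low_level_only"))
    stop_config("feature_config must be 'full' or 'low_level_only'")
  feature_config <- feature_config[1]
  img <- as_rgb_image(img)
  intensity <- compute_intensity(img)
  opp <- compute_opponency(img)
  channels <- list(I = intensity, RG = opp$RG, BY = opp$BY)
  orient_on <- function(base, suffix) {
    out <- lapply(bank$kernels, function(k) convolve2d_reflect(base, k))
    names(out) <- sprintf("O%d.%s", seq_along(out) - 1L, suffix)
    out
  }
  channels <- c(channels, orient_on(intensity, "I"))
  if (feature_config == "full")
    channels <- c(channels, orient_on(opp$RG, "RG"), orient_on(opp$BY, "BY"))
  structure(list(channels = channels, config = feature_config),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<feature_stack> %d channels (%s), %d x %d\n",
              length(x$channels), x$config, d[1], d[2]))
  invisible(x)
}
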