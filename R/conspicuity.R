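# Layer IV: CSF-weighted scale integration.
#
# Each feature's contrast maps are fused into a conspicuity map. The
# weight of each map follows the human contrast sensitivity function
# (Mannos-Sakrison form): globally as the mean CSF over the map's
# frequency grid, locally by modulating the map's spectrum with the CSF.
# A pyramid level covers larger visual angle per pixel the coarser it is,
# so the effective pixels-per-degree of a map scales with its resolution
# relative to the base image.

#' Contrast sensitivity function
#'
#' `C(f) = (0.0499 + 0.2964 f) * exp(-(0.114 f)^1.1)` with `f` in cycles
#' per degree of visual angle. Strictly positive, value 0.0499 at `f = 0`,
#' a single interior peak, and exponential decay at high frequency.
#'
#' @param f Spatial frequency in cycles/degree (vectorized, `>= 0`).
#' @return Sensitivity values, same length as `f`.
#' @export
#' @examples
#' csf(c(0, 4, 16))
csf <- function(f) {
  if (!is.numeric(f) || any(!is.finite(f)) || any(f < 0))
    stop_config("f must be non-negative and finite")
  (0.0499 + 0.2964 * f) * exp(-(0.114 * f)^1.1)
}

#' CSF evaluated on a 2-D DFT frequency grid
#'
#' Builds the matrix `C(f)` where `f` is the radial spatial frequency of
#' each Fourier bin of an H x W grid, converted from cycles/pixel to
#' cycles/degree via `pixels_per_degree`.
#'
#' @param shape Integer vector `c(H, W)`.
#' @param pixels_per_degree Viewing-geometry calibration (pixels spanning
#'   one degree of visual angle) for the grid at this resolution.
#' @return H x W matrix of sensitivities; the DC bin equals 0.0499.
#' @export
csf_matrix <- function(shape, pixels_per_degree) {
  shape <- as.integer(shape)
  if (length(shape) != 2 || any(shape < 1))
    stop_config("shape must be two positive integers")
  if (!is.numeric(pixels_per_degree) || length(pixels_per_degree) != 1 ||
      pixels_per_degree <= 0)
    stop_config("pixels_per_degree must be positive")
  freqs <- function(n) {
    k <- seq_len(n) - 1L
    k[k > n %/% 2] <- k[k > n %/% 2] - n   # signed DFT frequencies
    k / n                                  # cycles per pixel
  }
  fy <- freqs(shape[1]); fx <- freqs(shape[2])
  fr <- sqrt(outer(fy^2, fx^2, `+`)) * pixels_per_degree
  matrix(csf(fr), shape[1], shape[2])
}

# Effective pixels-per-degree of a map at `dim_map` given the calibration
# of the base grid: one map pixel spans base_rows/map_rows base pixels.
eff_ppd <- function(dim_map, base_dim, pixels_per_degree) {
  pixels_per_degree * dim_map[1] / base_dim[1]
}

#' Global conspicuity: CSF-weighted normalized sum of contrast maps
#'
#' Each map's scalar weight is the mean of the CSF matrix on its native
#' frequency grid; maps are resized bilinearly to `target_dim` and
#' combined as `sum(w_i m_i) / sum(w_i)` (a convex combination).
#'
#' @param maps List of contrast-map matrices for one feature.
#' @param ppd Numeric vector of effective pixels-per-degree, one per map.
#' @param target_dim Working resolution `c(H, W)` of the output.
#' @return Matrix at `target_dim`.
#' @export
global_conspicuity <- function(maps, ppd, target_dim) {
  check_consp_args(maps, ppd)
  w <- vapply(seq_along(maps),
              function(i) mean(csf_matrix(dim(maps[[i]]), ppd[i])), 0)
  if (sum(w) <= 0) stop_input("degenerate CSF weights (all zero)")
  acc <- matrix(0, target_dim[1], target_dim[2])
  for (i in seq_along(maps))
    acc <- acc + w[i] * resize_bilinear(maps[[i]], target_dim)
  acc / sum(w)
}

#' Local conspicuity: per-pixel CSF modulation of contrast maps
#'
#' Each map is transformed to the frequency domain, multiplied bin-wise by
#' its CSF matrix, inverse-transformed (real part, negatives clamped to
#' zero since sensitivity-filtered contrast is non-negative by intent),
#' resized to `target_dim`, and the maps are summed and divided by the sum
#' of the mean CSF values.
#'
#' @inheritParams global_conspicuity
#' @return Matrix at `target_dim`.
#' @export
local_conspicuity <- function(maps, ppd, target_dim) {
  check_consp_args(maps, ppd)
  denom <- 0
  acc <- matrix(0, target_dim[1], target_dim[2])
  for (i in seq_along(maps)) {
    cm <- csf_matrix(dim(maps[[i]]), ppd[i])
    denom <- denom + mean(cm)
    spec <- stats::fft(maps[[i]]) * cm
    mod <- Re(stats::fft(spec, inverse = TRUE)) / length(spec)
    mod[mod < 0] <- 0
    acc <- acc + resize_bilinear(mod, target_dim)
  }
  if (denom <= 0) stop_input("degenerate CSF weights (all zero)")
  acc / denom
}

check_consp_args <- function(maps, ppd) {
  if (!is.list(maps) || length(maps) < 1)
    stop_input("need at least one contrast map")
  if (length(ppd) != length(maps) || any(ppd <= 0))
    stop_config("ppd must supply one positive value per map")
  invisible(NULL)
}

#' Combine global and local conspicuity
#'
#' `alpha * global + beta * local` with the model defaults
#' `alpha = 0.95`, `beta = 0.05`.
#'
#' @param global,local Matrices of matching shape.
#' @param alpha,beta Non-negative mixing weights.
#' @return Object of class `conspicuity_map`: list with `values`,
#'   `components` (the two inputs), `alpha`, `beta`.
#' @export
combine_conspicuity <- function(global, local, alpha = 0.95, beta = 0.05) {
  assert_matrix(global, "global"); assert_matrix(local, "local")
  if (!identical(dim(global), dim(local)))
    stop_input("global and local conspicuity shapes differ")
  if (alpha < 0 || beta < 0) stop_config("alpha and beta must be >= 0")
  structure(list(values = alpha * global + beta * local,
                 components = list(global = global, local = local),
                 alpha = alpha, beta = beta),
            class = "conspicuity_map")
}

#' Conspicuity maps for every feature of a contrast-map set
#'
#' Applies the global and local CSF weighting per feature and mixes them.
#' All maps are fused at the resolution of scale 1 (the finest grid the
#' pyramid produces).
#'
#' @param cms A [build_contrast_maps()] result.
#' @param pixels_per_degree CSF calibration for the base image (default 32).
#' @param alpha,beta Mixing weights of global/local conspicuity.
#' @return Named list of conspicuity value matrices (one per feature),
#'   with attribute `config` recording the parameters.
#' @export
feature_conspicuity <- function(cms, pixels_per_degree = 32,
                                alpha = 0.95, beta = 0.05) {
  if (!inherits(cms, "contrast_map_set"))
    stop_input("cms must be a contrast_map_set")
  target_dim <- c(dwt_out_len(cms$base_dim[1]), dwt_out_len(cms$base_dim[2]))
  out <- lapply(cms$maps, function(feature_maps) {
    ppd <- vapply(feature_maps, function(m)
      eff_ppd(dim(m), cms$base_dim, pixels_per_degree), 0)
    g <- global_conspicuity(feature_maps, ppd, target_dim)
    l <- local_conspicuity(feature_maps, ppd, target_dim)
    combine_conspicuity(g, l, alpha, beta)$values
  })
  attr(out, "config") <- list(pixels_per_degree = pixels_per_degree,
                              alpha = alpha, beta = beta,
                              target_dim = target_dim)
  out
}
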