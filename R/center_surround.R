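# Layer III: center-surround difference maps.
#
# The center is a fine pyramid scale c, the surround a coarser scale
# s = c + delta (delta in {2, 3}); the surround is interpolated up to the
# center's grid and the absolute difference taken. Three scheme sizes
# (4, 6, 10 maps per feature) probe increasingly coarse image content.

.scheme_table <- list(
  `4`  = rbind(c(1, 3), c(1, 4), c(2, 4), c(2, 5)),
  `6`  = rbind(c(1, 3), c(1, 4), c(2, 4), c(2, 5), c(3, 5), c(3, 6)),
  `10` = rbind(c(1, 3), c(1, 4), c(2, 4), c(2, 5), c(3, 5), c(3, 6),
               c(4, 6), c(4, 7), c(5, 7), c(5, 8))
)

#' Center-surround scale pairs for a scheme size
#'
#' Returns the ordered list of (center, surround) scale pairs for the 4-,
#' 6-, or 10-map scheme. The schemes nest: each larger scheme extends the
#' previous one with pairs at coarser center scales.
#'
#' @param n_maps 4, 6 or 10.
#' @return Object of class `cs_scheme`: list with `n_maps` and `pairs`
#'   (n_maps x 2 integer matrix, columns `c` and `s`).
#' @export
#' @examples
#' scheme_pairs(4)$pairs
scheme_pairs <- function(n_maps) {
  key <- as.character(n_maps)
  if (length(n_maps) != 1 || !key %in% names(.scheme_table))
    stop_config("n_maps must be one of 4, 6, 10")
  pairs <- .scheme_table[[key]]
  colnames(pairs) <- c("c", "s")
  structure(list(n_maps = as.integer(n_maps), pairs = pairs),
            class = "cs_scheme")
}

#' Center-surround difference between two pyramid scales
#'
#' Interpolates the coarse scale `s` bilinearly up to the grid of the fine
#' scale `c` and returns the element-wise absolute difference.
#'
#' @param pyr A [decompose()] result.
#' @param c Center scale (fine), `1 <= c < s`.
#' @param s Surround scale (coarse), `s <= depth(pyr)`.
#' @return Non-negative matrix at the resolution of scale `c`.
#' @export
cs_difference <- function(pyr, c, s) {
  if (!inherits(pyr, "scale_pyramid")) stop_input("pyr must be a scale_pyramid")
  depth <- length(pyr$levels)
  if (length(c) != 1 || length(s) != 1 || c < 1 || s > depth || c >= s)
    stop_config("need 1 <= c < s <= %d, got c=%s s=%s", depth, c, s)
  center <- pyr$levels[[c]]
  surround <- resize_bilinear(pyr$levels[[s]], dim(center))
  abs(center - surround)
}

#' Build the full set of normalized contrast maps for a feature stack
#'
#' Decomposes every channel to the depth the scheme requires and computes
#' one min-max normalized center-surround map per (channel, scale pair).
#' With the full 27-channel stack this yields 108, 162 or 270 maps for the
#' 4-, 6- and 10-map schemes respectively.
#'
#' @param stack A [extract_features()] result.
#' @param scheme A [scheme_pairs()] result (or 4/6/10 for convenience).
#' @return Object of class `contrast_map_set`: list with `maps` (per
#'   feature, a list of `[0,1]` matrices with attributes `c` and `s`),
#'   `scheme`, `base_dim`.
#' @export
build_contrast_maps <- function(stack, scheme) {
  if (!inherits(stack, "feature_stack"))
    stop_input("stack must be a feature_stack")
  if (!inherits(scheme, "cs_scheme")) scheme <- scheme_pairs(scheme)
  depth <- max(scheme$pairs[, "s"])
  maps <- lapply(stack$channels, function(ch) {
    pyr <- decompose(ch, n_levels = depth)
    out <- lapply(seq_len(scheme$n_maps), function(i) {
      p <- scheme$pairs[i, ]
      m <- normalize01(cs_difference(pyr, p["c"], p["s"]))
      attr(m, "c") <- unname(p["c"]); attr(m, "s") <- unname(p["s"])
      m
    })
    names(out) <- sprintf("c%d.s%d", scheme$pairs[, "c"], scheme$pairs[, "s"])
    out
  })
  structure(list(maps = maps, scheme = scheme,
                 base_dim = dim(stack$channels[[1]])),
            class = "contrast_map_set")
}

#' Number of contrast maps in a set
#' @param cms A [build_contrast_maps()] result.
#' @return Integer count (n_channels x n_maps).
#' @export
n_contrast_maps <- function(cms) {
  if (!inherits(cms, "contrast_map_set"))
    stop_input("cms must be a contrast_map_set")
  sum(lengths(cms$maps))
}

#' @export
print.contrast_map_set <- function(x, ...) {
  cat(sprintf("<contrast_map_set> %d features x %d pairs = %d maps\n",
              length(x$maps), x$scheme$n_maps, n_contrast_maps(x)))
  invisible(x)
}
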