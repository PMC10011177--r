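# Layer II: Symlet-4 approximation pyramid.
#
# Each feature channel is decomposed by repeated separable 2-D DWT steps
# with the sym4 low-pass analysis filter; only the approximation sub-band
# is kept at each level. Detail sub-bands are discarded throughout.

# sym4 low-pass decomposition filter (standard published coefficients).
.sym4_dec_lo <- c(-0.07576571478927333, -0.02963552764599851,
                   0.49761866763201545,  0.80373875180591614,
                   0.29785779560527736, -0.09921954357684722,
                  -0.01260396726203783,  0.03222310060404270)

# Length of a DWT approximation for input length n under half-sample
# symmetric padding: floor((n + filter_len - 1) / 2).
dwt_out_len <- function(n) (n + length(.sym4_dec_lo) - 1L) %/% 2L

# One-dimensional decimated low-pass analysis operator as an m x n matrix:
# half-sample symmetric extension by (filter_len - 1) samples on each side,
# full convolution with the filter, downsampling by 2 phase-aligned with
# the common DWT convention. Cached per input length.
.dwt_op_cache <- new.env(parent = emptyenv())

dwt_operator <- function(n) {
  key <- as.character(n)
  hit <- .dwt_op_cache[[key]]
  if (!is.null(hit)) return(hit)
  g <- .sym4_dec_lo
  f <- length(g)
  p <- f - 1L
  m <- dwt_out_len(n)
  # padded index q (1 .. n + 2p) -> source index in 1..n
  src <- function(q) {
    ifelse(q <= p, p + 1L - q,
           ifelse(q <= p + n, q - p, 2L * n + p + 1L - q))
  }
  D <- matrix(0, m, n)
  for (i in seq_len(m)) {
    nfull <- f + 1L + 2L * (i - 1L)   # index into the full convolution
    for (j in seq_len(f)) {           # y[nfull] = sum_j g[j] * padded[nfull - j + 1]
      q <- nfull - j + 1L
      jj <- src(q)
      D[i, jj] <- D[i, jj] + g[j]
    }
  }
  .dwt_op_cache[[key]] <- D
  D
}

#' Wavelet approximation pyramid of a feature channel
#'
#' Repeatedly applies the separable 2-D sym4 low-pass analysis step and
#' keeps only the approximation coefficients. Each level is rescaled by
#' 1/2 (the orthonormal 2-D step doubles constants), so a constant input
#' stays the same constant at every level and cross-level differences live
#' on a common intensity scale. Scale 1 is the first-level approximation.
#'
#' @param channel Numeric matrix (one feature channel).
#' @param n_levels Pyramid depth (default 8).
#' @return Object of class `scale_pyramid`: list with `levels` (list of
#'   matrices, scale 1 .. n_levels) and `base_dim`.
#' @export
decompose <- function(channel, n_levels = 8) {
  assert_matrix(channel, "channel")
  if (!is.numeric(n_levels) || n_levels < 2 || n_levels != round(n_levels))
    stop_config("n_levels must be an integer >= 2")
  dims <- dim(channel)
  feasible <- 0L
  d <- dims
  repeat {
    nd <- c(dwt_out_len(d[1]), dwt_out_len(d[2]))
    if (any(d < 2)) break
    feasible <- feasible + 1L
    d <- nd
    if (feasible >= n_levels) break
  }
  if (feasible < n_levels)
    stop_input("channel of size %d x %d supports at most %d pyramid levels",
               dims[1], dims[2], feasible)
  levels <- vector("list", n_levels)
  a <- channel
  for (k in seq_len(n_levels)) {
    Dr <- dwt_operator(nrow(a))
    Dc <- dwt_operator(ncol(a))
    a <- 0.5 * (Dr %*% a %*% t(Dc))
    levels[[k]] <- a
  }
  structure(list(levels = levels, base_dim = dims), class = "scale_pyramid")
}

#' @export
print.scale_pyramid <- function(x, ...) {
  sizes <- vapply(x$levels, function(l) paste(dim(l), collapse = "x"), "")
  cat(sprintf("<scale_pyramid> %d levels from %s base: %s\n",
              length(x$levels), paste(x$base_dim, collapse = "x"),
              paste(sizes, collapse = ", ")))
  invisible(x)
}
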