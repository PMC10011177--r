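# Internal helpers shared across the pipeline.

stop_input <- function(msg, ...) {
  stop(structure(class = c("wavsal_input_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_config <- function(msg, ...) {
  stop(structure(class = c("wavsal_config_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

assert_matrix <- function(m, name = "matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    stop_input("%s must be a numeric matrix", name)
  if (!all(is.finite(m)))
    stop_input("%s contains non-finite values", name)
  invisible(m)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# stream; seed = NULL uses (and advances) the current stream.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Rescale a matrix to the unit interval
#'
#' Affine rescaling `(m - min) / (max - min)`. A constant input has no
#' contrast to rescale and maps to the all-zero matrix rather than dividing
#' by zero; a value range at floating-point noise level (below ~1e-13
#' relative to the magnitude) is treated as constant too, so arithmetic
#' dust from exactly uniform inputs is not amplified to full scale.
#'
#' @param m Numeric matrix with finite entries.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
#' @examples
#' normalize01(matrix(c(0, 2, 4, 8), 2))
normalize01 <- function(m) {
  assert_matrix(m, "input to normalize01")
  rng <- range(m)
  span <- rng[2] - rng[1]
  if (span <= 500 * .Machine$double.eps * max(abs(rng), 1))
    return(array(0, dim(m)))
  (m - rng[1]) / span
}

# Row-interpolation operator: out_n x in_n matrix W such that W %*% v
# linearly interpolates v at output pixel centers (centers aligned:
# output center i sits at input coordinate (i - 0.5) * in_n/out_n + 0.5).
interp_operator <- function(in_n, out_n) {
  pos <- (seq_len(out_n) - 0.5) * in_n / out_n + 0.5
  pos <- pmin(pmax(pos, 1), in_n)
  lo <- pmin(floor(pos), in_n - 1L)
  if (in_n == 1L) lo <- rep(1L, out_n)
  frac <- pos - lo
  W <- matrix(0, out_n, in_n)
  idx <- cbind(seq_len(out_n), lo)
  W[idx] <- W[idx] + (1 - frac)
  idx2 <- cbind(seq_len(out_n), pmin(lo + 1L, in_n))
  W[idx2] <- W[idx2] + frac
  W
}

#' Bilinear image resizing
#'
#' Resizes a matrix (or H x W x C array, channel-wise) to `out_dim` by
#' separable linear interpolation with pixel-center alignment.
#'
#' @param m Numeric matrix or 3-d array.
#' @param out_dim Integer vector `c(rows, cols)`.
#' @return Resized matrix/array.
#' @export
resize_bilinear <- function(m, out_dim) {
  out_dim <- as.integer(out_dim)
  if (length(out_dim) != 2 || any(out_dim < 1))
    stop_input("out_dim must be two positive integers")
  if (length(dim(m)) == 3) {
    out <- array(0, c(out_dim, dim(m)[3]))
    for (ch in seq_len(dim(m)[3]))
      out[, , ch] <- resize_bilinear(m[, , ch], out_dim)
    return(out)
  }
  assert_matrix(m, "input to resize_bilinear")
  if (all(dim(m) == out_dim)) return(m)
  Wr <- interp_operator(nrow(m), out_dim[1])
  Wc <- interp_operator(ncol(m), out_dim[2])
  Wr %*% m %*% t(Wc)
}

# 2-D convolution with reflect (whole-sample mirror) padding, FFT-based.
# Kernel dimensions must be odd.
convolve2d_reflect <- function(m, k) {
  kh <- nrow(k); kw <- ncol(k)
  stopifnot(kh %% 2 == 1, kw %% 2 == 1)
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  H <- nrow(m); W <- ncol(m)
  ri <- c(rev(seq_len(min(ph, H - 1)) + 1L), seq_len(H),
          H - seq_len(min(ph, H - 1)))
  ci <- c(rev(seq_len(min(pw, W - 1)) + 1L), seq_len(W),
          W - seq_len(min(pw, W - 1)))
  if (length(ri) < H + 2 * ph || length(ci) < W + 2 * pw)
    stop_input("image too small for the kernel")
  padded <- m[ri, ci, drop = FALSE]
  PH <- nrow(padded); PW <- ncol(padded)
  kp <- matrix(0, PH, PW)
  kp[seq_len(kh), seq_len(kw)] <- k
  conv <- Re(stats::fft(stats::fft(padded) * stats::fft(kp), inverse = TRUE)) /
    (PH * PW)
  conv[(2 * ph + 1):(2 * ph + H), (2 * pw + 1):(2 * pw + W), drop = FALSE]
}
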