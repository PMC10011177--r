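# Independent brute-force oracles used to cross-check the implementation.
# Each oracle recomputes the target quantity by direct enumeration or a
# closed form, never through the code path it checks.

# Bilinear interpolation by explicit per-pixel arithmetic (pixel-center
# aligned, clamped at the borders).
brute_bilinear <- function(m, out_dim) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, out_dim[1], out_dim[2])
  for (i in seq_len(out_dim[1])) for (j in seq_len(out_dim[2])) {
    y <- min(max((i - 0.5) * H / out_dim[1] + 0.5, 1), H)
    x <- min(max((j - 0.5) * W / out_dim[2] + 0.5, 1), W)
    y0 <- min(floor(y), H - 1); x0 <- min(floor(x), W - 1)
    if (H == 1) y0 <- 1
    if (W == 1) x0 <- 1
    fy <- y - y0; fx <- x - x0
    y1 <- min(y0 + 1, H); x1 <- min(x0 + 1, W)
    out[i, j] <- (1 - fy) * (1 - fx) * m[y0, x0] + (1 - fy) * fx * m[y0, x1] +
                 fy * (1 - fx) * m[y1, x0] + fy * fx * m[y1, x1]
  }
  out
}

# ROC area by the Mann-Whitney pair count with half credit for ties --
# a closed form independent of any threshold sweep.
brute_auc <- function(pos, neg) {
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Explicit O(N^2) 2-D DFT, per-bin product with a transfer matrix, and
# inverse DFT (real part).
brute_dft_modulate <- function(m, transfer) {
  H <- nrow(m); W <- ncol(m)
  Fm <- matrix(0i, H, W)
  for (u in 0:(H - 1)) for (v in 0:(W - 1)) {
    acc <- 0i
    for (r in 0:(H - 1)) for (c in 0:(W - 1))
      acc <- acc + m[r + 1, c + 1] * exp(-2i * pi * (u * r / H + v * c / W))
    Fm[u + 1, v + 1] <- acc
  }
  Fm <- Fm * transfer
  out <- matrix(0, H, W)
  for (r in 0:(H - 1)) for (c in 0:(W - 1)) {
    acc <- 0i
    for (u in 0:(H - 1)) for (v in 0:(W - 1))
      acc <- acc + Fm[u + 1, v + 1] * exp(2i * pi * (u * r / H + v * c / W))
    out[r + 1, c + 1] <- Re(acc) / (H * W)
  }
  out
}

# Local maxima by exhaustive window scan (strict: >= all neighbors and
# > at least one value in the matrix), without plateau collapsing.
brute_local_maxima <- function(m, nb = 3) {
  r <- (nb - 1) / 2
  H <- nrow(m); W <- ncol(m)
  res <- NULL
  for (i in seq_len(H)) for (j in seq_len(W)) {
    win <- m[max(1, i - r):min(H, i + r), max(1, j - r):min(W, j + r)]
    if (m[i, j] >= max(win) && m[i, j] > min(m))
      res <- rbind(res, c(i, j))
  }
  res
}

# Fine-grid maximizer of a 1-D function.
grid_peak <- function(fn, lo, hi, n = 200001) {
  xs <- seq(lo, hi, length.out = n)
  ys <- fn(xs)
  xs[which.max(ys)]
}

# Small deterministic RGB test image.
toy_rgb <- function(H = 48, W = 64, seed = 7) {
  withr::with_seed(seed, array(stats::runif(H * W * 3), c(H, W, 3)))
}

argmax_in_box <- function(values, box) {
  am <- which(values == max(values), arr.ind = TRUE)[1, ]
  am[1] >= box[1] && am[1] <= box[2] && am[2] >= box[3] && am[2] <= box[4]
}

box_energy <- function(channel, box) {
  mean(abs(channel[box[1]:box[2], box[3]:box[4]]))
}

# Element bounding boxes of a bar-grid stimulus (half-width matches the
# bar length used by render_stimulus).
grid_boxes <- function(spec) {
  half <- spec$element_size %/% 2 + 2L
  H <- spec$frame[1]; W <- spec$frame[2]
  out <- list()
  for (gi in seq_len(spec$grid[1])) for (gj in seq_len(spec$grid[2])) {
    cy <- round((gi - 0.5) * H / spec$grid[1])
    cx <- round((gj - 0.5) * W / spec$grid[2])
    out[[length(out) + 1]] <- list(
      box = c(max(1, cy - half), min(H, cy + half),
              max(1, cx - half), min(W, cx + half)),
      is_target = gi == spec$target_cell[1] && gj == spec$target_cell[2])
  }
  out
}
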