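# Synthetic pop-out stimuli and fixations.
#
# Visual-search displays with a single target among homogeneous
# distractors exercise every stage of the pipeline with known ground
# truth: color pop-out drives the opponency channels, orientation pop-out
# the Gabor channels, and the conjunction target (unique only in the
# combination color x orientation) specifically requires the medium-level
# channels. Two texture fixtures probe the content dependence of the
# center-surround scheme: a fine-texture target is carried by fine-scale
# contrasts, a large smooth blob by coarse-scale ones.

#' Specification of a synthetic stimulus
#'
#' @param kind One of `"color_popout"`, `"orientation_popout"`,
#'   `"conjunction_popout"`, `"uniform"`, `"noise"`, `"fine_texture"`,
#'   `"large_blob"`.
#' @param frame `c(H, W)` of the rendered image (default `c(225, 400)`).
#' @param grid `c(rows, cols)` of search elements (bar kinds only).
#' @param target_cell `c(row, col)` grid cell of the target.
#' @param element_size Bar length in pixels (default 30, about three Gabor
#'   wavelengths so the orientation channels respond strongly).
#' @param seed Integer seed (used by the noise kind; recorded for
#'   reproducibility elsewhere).
#' @return Object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(kind, frame = c(225L, 400L), grid = c(3L, 5L),
                          target_cell = c(2L, 2L), element_size = 30L,
                          seed = 1L) {
  kinds <- c("color_popout", "orientation_popout", "conjunction_popout",
             "uniform", "noise", "fine_texture", "large_blob")
  if (!is.character(kind) || !kind %in% kinds)
    stop_config("kind must be one of: %s", paste(kinds, collapse = ", "))
  frame <- as.integer(frame); grid <- as.integer(grid)
  target_cell <- as.integer(target_cell)
  if (any(frame < 32)) stop_config("frame must be at least 32 x 32")
  if (any(grid < 1) || prod(grid) < 2)
    stop_config("grid must contain at least two cells")
  if (any(target_cell < 1) || any(target_cell > grid))
    stop_config("target_cell outside the %d x %d grid", grid[1], grid[2])
  if (element_size < 8) stop_config("element_size must be >= 8 pixels")
  structure(list(kind = kind, frame = frame, grid = grid,
                 target_cell = target_cell,
                 element_size = as.integer(element_size),
                 seed = as.integer(seed)),
            class = "stimulus_spec")
}

# Luminance-matched bar colors (equal intensity-channel response):
# red (1, 0, 0) and green (0, 0.2989/0.5870, 0).
.bar_red <- c(1, 0, 0)
.bar_green <- c(0, 0.2989 / 0.5870, 0)
.bar_gray <- rep(0.2989, 3)   # same intensity as the red bar
.bg_gray <- 0.5

paint_rect <- function(img, rows, cols, color) {
  rows <- rows[rows >= 1 & rows <= dim(img)[1]]
  cols <- cols[cols >= 1 & cols <= dim(img)[2]]
  for (ch in 1:3) img[rows, cols, ch] <- color[ch]
  img
}

checker_patch <- function(h, w, period, lo, hi) {
  blk <- (outer(seq_len(h) - 1, seq_len(w) - 1,
                function(r, c) ((r %/% (period / 2)) + (c %/% (period / 2))) %% 2))
  lo + (hi - lo) * blk
}

gauss_blob <- function(frame, center, sigma) {
  d2 <- outer((seq_len(frame[1]) - center[1])^2,
              (seq_len(frame[2]) - center[2])^2, `+`)
  exp(-d2 / (2 * sigma^2))
}

#' Render a synthetic stimulus
#'
#' Bar displays place one element per grid cell on a mid-gray background;
#' the target differs from the distractors in the dimension(s) the kind
#' specifies. The conjunction display alternates red-vertical and
#' green-horizontal distractors (red and green luminance-matched) around
#' a red-horizontal target, so the target is unique in no single low-level
#' dimension. The texture kinds embed a fine checkerboard patch (among
#' large faint luminance blobs) or a large smooth blob (among small
#' high-frequency clutter patches).
#'
#' @param spec A [stimulus_spec()].
#' @return List with `image` (H x W x 3), `target_box`
#'   (`c(row_min, row_max, col_min, col_max)`, NULL for uniform/noise) and
#'   `spec`.
#' @export
render_stimulus <- function(spec) {
  if (!inherits(spec, "stimulus_spec")) stop_input("spec must be a stimulus_spec")
  H <- spec$frame[1]; W <- spec$frame[2]
  img <- array(.bg_gray, c(H, W, 3))
  box <- NULL
  if (spec$kind == "uniform") {
    # constant image: nothing is salient
  } else if (spec$kind == "noise") {
    n <- with_seed_(spec$seed, matrix(stats::runif(H * W), H, W))
    for (ch in 1:3) img[, , ch] <- n
  } else if (spec$kind %in% c("color_popout", "orientation_popout",
                              "conjunction_popout")) {
    L <- spec$element_size
    Wd <- max(4L, round(L / 4))
    cell_h <- H / spec$grid[1]; cell_w <- W / spec$grid[2]
    for (gi in seq_len(spec$grid[1])) for (gj in seq_len(spec$grid[2])) {
      cy <- round((gi - 0.5) * cell_h); cx <- round((gj - 0.5) * cell_w)
      is_target <- gi == spec$target_cell[1] && gj == spec$target_cell[2]
      style <- switch(spec$kind,
        color_popout = list(col = if (is_target) .bar_red else .bar_gray,
                            horiz = TRUE),
        orientation_popout = list(col = .bar_gray, horiz = is_target),
        conjunction_popout = {
          if (is_target) list(col = .bar_red, horiz = TRUE)
          else if ((gi + gj) %% 2 == 0) list(col = .bar_red, horiz = FALSE)
          else list(col = .bar_green, horiz = TRUE)
        })
      half_l <- L %/% 2; half_w <- Wd %/% 2
      if (style$horiz) {
        rows <- (cy - half_w):(cy + half_w); cols <- (cx - half_l):(cx + half_l)
      } else {
        rows <- (cy - half_l):(cy + half_l); cols <- (cx - half_w):(cx + half_w)
      }
      img <- paint_rect(img, rows, cols, style$col)
      if (is_target)
        box <- c(max(1, min(rows)), min(H, max(rows)),
                 max(1, min(cols)), min(W, max(cols)))
    }
  } else if (spec$kind == "fine_texture") {
    # fine checkerboard target among large faint luminance blobs; the
    # checker period (8 px) is fine relative to the blobs but coarse
    # enough to survive the first pyramid low-pass, so the target lives
    # in the scale-1/2 contrasts that the 4-map scheme is built from
    ph <- 32L; pw <- 32L
    r0 <- round(H * 0.28); c0 <- round(W * 0.62)
    patch <- checker_patch(ph, pw, 8, .bg_gray - 0.25, .bg_gray + 0.25)
    base <- matrix(.bg_gray, H, W)
    for (b in list(c(0.75, 0.2, 30), c(0.3, 0.15, 25), c(0.7, 0.8, 28)))
      base <- base + 0.08 * gauss_blob(spec$frame,
                                       c(b[1] * H, b[2] * W), b[3])
    base[r0:(r0 + ph - 1), c0:(c0 + pw - 1)] <- patch
    base <- pmin(pmax(base, 0), 1)
    for (ch in 1:3) img[, , ch] <- base
    box <- c(r0, r0 + ph - 1, c0, c0 + pw - 1)
  } else if (spec$kind == "large_blob") {
    # large smooth blob target among small high-frequency clutter patches
    center <- c(round(H * 0.6), round(W * 0.3)); sigma <- 40
    base <- matrix(.bg_gray, H, W) + 0.35 * gauss_blob(spec$frame, center, sigma)
    for (p in list(c(0.2, 0.65), c(0.8, 0.75), c(0.25, 0.9))) {
      pr <- round(p[1] * H); pc <- round(p[2] * W)
      pr2 <- min(pr + 23L, H); pc2 <- min(pc + 23L, W)
      base[pr:pr2, pc:pc2] <-
        checker_patch(pr2 - pr + 1L, pc2 - pc + 1L, 8,
                      .bg_gray - 0.25, .bg_gray + 0.25)
    }
    base <- pmin(pmax(base, 0), 1)
    for (ch in 1:3) img[, , ch] <- base
    half <- round(sigma)   # the blob core; fixations concentrate here
    box <- c(max(1, center[1] - half), min(H, center[1] + half),
             max(1, center[2] - half), min(W, center[2] + half))
  }
  list(image = img, target_box = box, spec = spec)
}

#' Sample synthetic fixations around a target
#'
#' Draws `n_on_target` fixations uniformly inside the target box and
#' `n_background` uniformly over the rest of the frame.
#'
#' @param target_box `c(row_min, row_max, col_min, col_max)` or NULL (all
#'   fixations uniform over the frame).
#' @param frame `c(H, W)`.
#' @param n_on_target,n_background Counts (total must be >= 1).
#' @param seed Integer seed for reproducibility.
#' @return A [fixation_set()].
#' @export
sample_fixations <- function(target_box, frame, n_on_target = 60,
                             n_background = 15, seed = 1L) {
  frame <- as.integer(frame)
  if (n_on_target + n_background < 1) stop_config("need at least one fixation")
  if (!is.null(target_box)) {
    if (target_box[1] < 1 || target_box[2] > frame[1] ||
        target_box[3] < 1 || target_box[4] > frame[2] ||
        target_box[1] > target_box[2] || target_box[3] > target_box[4])
      stop_input("target_box outside the frame")
  } else {
    n_background <- n_on_target + n_background
    n_on_target <- 0
  }
  with_seed_(seed, {
    pts <- matrix(0L, 0, 2)
    if (n_on_target > 0) {
      pts <- cbind(
        sample(target_box[1]:target_box[2], n_on_target, replace = TRUE),
        sample(target_box[3]:target_box[4], n_on_target, replace = TRUE))
    }
    bg <- matrix(0L, 0, 2)
    while (nrow(bg) < n_background) {
      cand <- cbind(sample.int(frame[1], n_background, replace = TRUE),
                    sample.int(frame[2], n_background, replace = TRUE))
      if (!is.null(target_box)) {
        inside <- cand[, 1] >= target_box[1] & cand[, 1] <= target_box[2] &
                  cand[, 2] >= target_box[3] & cand[, 2] <= target_box[4]
        cand <- cand[!inside, , drop = FALSE]
      }
      bg <- rbind(bg, cand)
    }
    fixation_set(rbind(pts, bg[seq_len(n_background), , drop = FALSE]), frame)
  })
}

#' Build the standard synthetic fixture battery
#'
#' Seven reproducible image/fixation pairs: uniform, noise, the three
#' pop-out kinds, a fine-texture image (whose target lives in fine-scale
#' contrast, favoring the 4-map scheme) and a large-blob image (whose
#' target lives in coarse-scale contrast, favoring the 10-map scheme).
#' Target fixtures receive fixations concentrated on the target (80% on
#' target); uniform and noise receive uniform fixations.
#'
#' @param seed Integer master seed; each fixture derives its own sub-seed.
#' @param frame `c(H, W)` of the rendered images.
#' @return Named list of fixtures, each a list with `name`, `image`,
#'   `target_box`, `fixations`, `spec`.
#' @export
make_fixture_suite <- function(seed = 1L, frame = c(225L, 400L)) {
  kinds <- c("uniform", "noise", "color_popout", "orientation_popout",
             "conjunction_popout", "fine_texture", "large_blob")
  out <- lapply(seq_along(kinds), function(i) {
    sub_seed <- (as.integer(seed) + 1000L * i) %% .Machine$integer.max
    spec <- stimulus_spec(kinds[i], frame = frame, seed = sub_seed)
    st <- render_stimulus(spec)
    fix <- if (is.null(st$target_box))
      sample_fixations(NULL, frame, 0, 75, seed = sub_seed + 1L)
    else
      sample_fixations(st$target_box, frame, 60, 15, seed = sub_seed + 1L)
    list(name = kinds[i], image = st$image, target_box = st$target_box,
         fixations = fix, spec = spec)
  })
  names(out) <- kinds
  out
}
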