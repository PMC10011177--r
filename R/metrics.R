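# Fixation-prediction metrics: AUC-Borji and shuffled AUC.
#
# Fixated pixels are positives; negatives are random pixels (AUC-Borji)
# or fixations pooled from other images (sAUC, which penalizes center
# bias because other images' fixations share the central tendency). The
# ROC is swept over all observed saliency values; ties contribute half,
# so an uninformative constant map scores exactly 0.5.

#' Fixation set
#'
#' A set of fixated pixel coordinates within an image frame. Coordinates
#' are 1-based (row, col) with origin at the top-left; duplicates are
#' allowed (multiple observers).
#'
#' @param points Integer matrix/data frame with columns row, col (k x 2).
#' @param frame Integer vector `c(H, W)`.
#' @return Object of class `fixation_set`.
#' @export
fixation_set <- function(points, frame) {
  frame <- as.integer(frame)
  if (length(frame) != 2 || any(frame < 1))
    stop_input("frame must be two positive integers")
  points <- as.matrix(points)
  if (length(points) == 0) points <- matrix(0L, 0, 2)
  if (ncol(points) != 2) stop_input("points must have two columns (row, col)")
  storage.mode(points) <- "integer"
  if (nrow(points) > 0 &&
      (min(points) < 1 || any(points[, 1] > frame[1]) ||
       any(points[, 2] > frame[2])))
    stop_input("fixation coordinates outside the %d x %d frame",
               frame[1], frame[2])
  colnames(points) <- c("row", "col")
  structure(list(points = points, frame = frame), class = "fixation_set")
}

#' @export
print.fixation_set <- function(x, ...) {
  cat(sprintf("<fixation_set> %d points in %d x %d frame\n",
              nrow(x$points), x$frame[1], x$frame[2]))
  invisible(x)
}

#' Read fixations from a CSV file
#'
#' Expects a header with columns `x,y` where `x` is the 1-based column
#' (horizontal, left to right) and `y` the 1-based row (vertical, top
#' down) -- the common convention of fixation datasets.
#'
#' @param path CSV path.
#' @param frame `c(H, W)` of the image the fixations belong to.
#' @return A [fixation_set()].
#' @export
read_fixations_csv <- function(path, frame) {
  if (!file.exists(path)) stop_input("fixation file not found: %s", path)
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df)))
    stop_input("fixation CSV must have columns x,y")
  fixation_set(cbind(row = round(df$y), col = round(df$x)), frame)
}

#' Write fixations to CSV (columns `x,y`, x = column)
#' @param fix A [fixation_set()].
#' @param path Output path.
#' @export
write_fixations_csv <- function(fix, path) {
  if (!inherits(fix, "fixation_set")) stop_input("fix must be a fixation_set")
  utils::write.csv(data.frame(x = fix$points[, "col"],
                              y = fix$points[, "row"]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Fixations from a binary map image
#'
#' Nonzero pixels of a grayscale PNG (or matrix) are taken as fixation
#' locations.
#'
#' @param map Matrix or path to a PNG.
#' @return A [fixation_set()] in the map's own frame.
#' @export
fixations_from_map <- function(map) {
  if (is.character(map)) {
    m <- png::readPNG(map)
    if (length(dim(m)) == 3) m <- m[, , 1]
    map <- m
  }
  assert_matrix(map, "fixation map")
  idx <- which(map != 0, arr.ind = TRUE)
  fixation_set(idx, dim(map))
}

# Trapezoidal ROC area for given positive/negative saliency samples,
# sweeping thresholds over all observed values; ties contribute half.
roc_area <- function(pos, neg) {
  th <- sort(unique(c(pos, neg)), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(pos >= t), 0)
  fpr <- vapply(th, function(t) mean(neg >= t), 0)
  tpr <- c(0, tpr, 1); fpr <- c(0, fpr, 1)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

sal_values_at <- function(sal, fix) {
  m <- as_saliency_matrix(sal)
  if (!identical(dim(m), as.integer(fix$frame)))
    m <- resize_bilinear(m, fix$frame)
  list(m = m, pos = m[fix$points])
}

new_auc_result <- function(scores, n_neg, seed) {
  structure(list(score = mean(scores), split_scores = scores,
                 n_splits = length(scores), n_negatives_per_split = n_neg,
                 seed = seed),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("<auc_result> score %.4f over %d splits (%d negatives each)\n",
              x$score, x$n_splits, x$n_negatives_per_split))
  invisible(x)
}

#' AUC-Borji fixation-prediction score
#'
#' For each of `n_splits` random splits, as many negative pixels as there
#' are fixations are sampled uniformly at random over the image frame and
#' the trapezoidal ROC area between the saliency values at fixations and
#' at negatives is computed; the score is the mean over splits. The map is
#' resized to the fixation frame if needed. Invariant under strictly
#' increasing transforms of the map.
#'
#' @param sal Saliency matrix or `saliency_map`.
#' @param fix A [fixation_set()] with at least one point.
#' @param n_splits Number of negative resamplings (default 100).
#' @param seed Optional integer for reproducible sampling.
#' @return An `auc_result` (fields `score`, `split_scores`, ...).
#' @export
auc_borji <- function(sal, fix, n_splits = 100, seed = NULL) {
  if (!inherits(fix, "fixation_set") || nrow(fix$points) == 0)
    stop_input("non-empty fixation_set required")
  sv <- sal_values_at(sal, fix)
  n <- length(sv$pos)
  npx <- prod(fix$frame)
  scores <- with_seed_(seed, vapply(seq_len(n_splits), function(i) {
    neg <- sv$m[sample.int(npx, n, replace = TRUE)]
    roc_area(sv$pos, neg)
  }, 0))
  new_auc_result(scores, n, seed)
}

#' Shuffled AUC (sAUC) fixation-prediction score
#'
#' As [auc_borji()], but negatives are drawn from fixations on *other*
#' images, so a map that merely reproduces the shared spatial bias of
#' fixations (e.g. center bias) scores near 0.5. Negatives are sampled
#' without replacement per split when the pool is large enough, with
#' replacement (and a warning) otherwise.
#'
#' @inheritParams auc_borji
#' @param other_fix A [fixation_set()] or list of them: the pool of
#'   other-image fixations (coordinates are reused in this image's frame).
#' @return An `auc_result`.
#' @export
sauc <- function(sal, fix, other_fix, n_splits = 100, seed = NULL) {
  if (!inherits(fix, "fixation_set") || nrow(fix$points) == 0)
    stop_input("non-empty fixation_set required")
  if (inherits(other_fix, "fixation_set")) other_fix <- list(other_fix)
  pool <- do.call(rbind, lapply(other_fix, function(f) {
    if (!inherits(f, "fixation_set")) stop_input("other_fix must be fixation_sets")
    f$points
  }))
  if (is.null(pool) || nrow(pool) == 0)
    stop_input("other-image fixation pool is empty")
  pool[, 1] <- pmin(pool[, 1], fix$frame[1])
  pool[, 2] <- pmin(pool[, 2], fix$frame[2])
  sv <- sal_values_at(sal, fix)
  n <- length(sv$pos)
  replace <- nrow(pool) < n
  if (replace)
    warning("other-fixation pool smaller than the positive set; ",
            "sampling negatives with replacement")
  scores <- with_seed_(seed, vapply(seq_len(n_splits), function(i) {
    idx <- sample.int(nrow(pool), n, replace = replace)
    neg <- sv$m[pool[idx, , drop = FALSE]]
    roc_area(sv$pos, neg)
  }, 0))
  new_auc_result(scores, n, seed)
}
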