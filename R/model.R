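# Orchestration of the five processing layers into the three published
# model versions:
#   version 1 - low-level features only, fixed 6-map scheme;
#   version 2 - adds the 16 medium-level features, fixed 6-map scheme;
#   version 3 - full features with all three schemes (4, 6, 10), the best
#               scheme being selected per image at evaluation time.

#' Model configuration
#'
#' Validates and completes a configuration for [run_model()]. Version
#' constraints are enforced: version 1 implies low-level features and the
#' 6-map scheme; version 2 full features and the 6-map scheme; version 3
#' full features and all of the 4/6/10 schemes.
#'
#' @param version Model version 1, 2 or 3 (default 2).
#' @param integration_method Feature integration method 1-4 (default 4).
#' @param alpha,beta Global/local conspicuity mixing weights
#'   (defaults 0.95 / 0.05).
#' @param pixels_per_degree CSF calibration of the working-size image
#'   (default 32).
#' @param working_size `c(H, W)` the input is resized to before
#'   processing (default `c(450, 800)`).
#' @param gabor_wavelength Gabor carrier wavelength in pixels (default 10).
#' @return Object of class `model_config`.
#' @export
model_config <- function(version = 2L, integration_method = 4L,
                         alpha = 0.95, beta = 0.05,
                         pixels_per_degree = 32,
                         working_size = c(450L, 800L),
                         gabor_wavelength = 10) {
  if (!version %in% 1:3) stop_config("version must be 1, 2 or 3")
  if (!integration_method %in% 1:4)
    stop_config("integration_method must be in 1..4")
  if (alpha < 0 || beta < 0) stop_config("alpha and beta must be >= 0")
  if (pixels_per_degree <= 0) stop_config("pixels_per_degree must be positive")
  working_size <- as.integer(working_size)
  if (length(working_size) != 2 || any(working_size < 16))
    stop_config("working_size must be two integers >= 16")
  cfg <- list(
    version = as.integer(version),
    feature_config = if (version == 1L) "low_level_only" else "full",
    schemes = if (version == 3L) c(4L, 6L, 10L) else 6L,
    integration_method = as.integer(integration_method),
    alpha = alpha, beta = beta,
    pixels_per_degree = pixels_per_degree,
    working_size = working_size,
    gabor_wavelength = gabor_wavelength)
  structure(cfg, class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(paste0("<model_config> version %d (%s), scheme(s) %s, ",
                     "method %d, alpha=%.2f beta=%.2f, ppd=%g, work %dx%d\n"),
              x$version, x$feature_config,
              paste(x$schemes, collapse = "/"), x$integration_method,
              x$alpha, x$beta, x$pixels_per_degree,
              x$working_size[1], x$working_size[2]))
  invisible(x)
}

#' Run the saliency model on an image
#'
#' Resizes the image to the working size, extracts the feature stack,
#' builds the contrast maps for each configured scheme, fuses scales into
#' conspicuity maps and integrates features into the final saliency
#' map(s), resized back to the input resolution.
#'
#' @param img H x W x 3 array in `[0, 1]` (see [read_image()]), or a
#'   matrix treated as grayscale.
#' @param cfg A [model_config()] (default: version 2).
#' @return Object of class `model_output`: list with `saliency` (a single
#'   `saliency_map` for versions 1-2; for version 3 a list keyed "4", "6",
#'   "10"), `counts` (channels and contrast maps per scheme), `config`.
#' @export
run_model <- function(img, cfg = model_config()) {
  if (!inherits(cfg, "model_config")) stop_config("cfg must be a model_config")
  img <- as_rgb_image(img)
  in_dim <- dim(img)[1:2]
  work <- resize_bilinear(img, cfg$working_size)
  work[work < 0] <- 0; work[work > 1] <- 1   # interpolation can overshoot at edges
  bank <- make_gabor_bank(cfg$gabor_wavelength, 8)
  stack <- extract_features(work, cfg$feature_config, bank)
  per_scheme <- lapply(cfg$schemes, function(nm) {
    cms <- build_contrast_maps(stack, scheme_pairs(nm))
    cmaps <- feature_conspicuity(cms, cfg$pixels_per_degree,
                                 cfg$alpha, cfg$beta)
    sal <- integrate_features(cmaps, cfg$integration_method)
    sal$values <- normalize01(resize_bilinear(sal$values, in_dim))
    sal$provenance$model_version <- cfg$version
    sal$provenance$n_maps <- nm
    list(sal = sal, n_contrast = n_contrast_maps(cms))
  })
  names(per_scheme) <- as.character(cfg$schemes)
  counts <- list(n_channels = length(stack$channels),
                 n_contrast_maps = vapply(per_scheme, `[[`, 0L, "n_contrast"))
  saliency <- if (cfg$version == 3L) lapply(per_scheme, `[[`, "sal")
              else per_scheme[[1]]$sal
  structure(list(saliency = saliency, counts = counts, config = cfg),
            class = "model_output")
}

#' @export
print.model_output <- function(x, ...) {
  cat(sprintf("<model_output> version %d, %d channels, contrast maps: %s\n",
              x$config$version, x$counts$n_channels,
              paste(x$counts$n_contrast_maps, collapse = "/")))
  invisible(x)
}

#' Select the best scheme of a version-3 run against fixations
#'
#' Scores each per-scheme saliency map with the given metric and returns
#' the scheme achieving the maximum score (ties resolve to the smallest
#' scheme).
#'
#' @param maps Named list of `saliency_map`s keyed by scheme size (as in
#'   the `saliency` slot of a version-3 [run_model()] output).
#' @param fix A [fixation_set()].
#' @param metric A function `(sal, fix, ...) -> auc_result` such as
#'   [auc_borji()]; additional arguments are passed through.
#' @param ... Passed to `metric` (e.g. `seed`, `n_splits`, `other_fix`).
#' @return List with `best_scheme`, `best_score` and the named `scores`
#'   vector.
#' @export
evaluate_version3 <- function(maps, fix, metric = auc_borji, ...) {
  if (!is.list(maps) || length(maps) < 1) stop_input("maps must be a list")
  if (!inherits(fix, "fixation_set") || nrow(fix$points) == 0)
    stop_input("non-empty fixation_set required")
  scores <- vapply(maps, function(m) metric(m, fix, ...)$score, 0)
  best <- which.max(scores)   # first maximum: smallest scheme on ties
  list(best_scheme = as.integer(names(maps)[best]),
       best_score = unname(scores[best]),
       scores = scores)
}

#' Convenience mean map for a version-3 run without fixations
#'
#' When no fixations are available to select a scheme, the three
#' per-scheme maps can be summarized by their rescaled mean. This
#' aggregate is a convenience output of this package, not part of the
#' published model, which selects the best scheme by score.
#'
#' @inheritParams evaluate_version3
#' @return A `saliency_map` (method tagged "mean-of-schemes").
#' @export
mean_scheme_map <- function(maps) {
  vals <- lapply(maps, function(m) m$values)
  check_cmaps(vals)
  new_saliency_map(normalize01(Reduce(`+`, vals) / length(vals)),
                   maps[[1]]$provenance$integration_method,
                   list(aggregate = "mean-of-schemes"))
}
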