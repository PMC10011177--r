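#' Read an RGB image from PNG or JPEG
#'
#' Decodes an image file into an H x W x 3 array of reals in `[0, 1]`
#' (8- and 16-bit inputs are normalized by the decoder). Grayscale images
#' are replicated across the three channels; an alpha channel is dropped.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return H x W x 3 numeric array in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_input("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop_input("unsupported image format '%s' (PNG or JPEG expected)", ext))
  as_rgb_image(img)
}

#' Coerce an array to a valid RGB image
#'
#' Accepts an H x W matrix (replicated to three channels) or an H x W x C
#' array with C in {1, 2, 3, 4}; alpha channels are dropped.
#'
#' @param img Numeric matrix or array, values in `[0, 1]`.
#' @return H x W x 3 numeric array.
#' @export
as_rgb_image <- function(img) {
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  d <- dim(img)
  if (length(d) != 3) stop_input("image must be an H x W x C array")
  if (d[3] == 2L) img <- img[, , 1L, drop = FALSE]      # gray + alpha
  if (d[3] == 4L) img <- img[, , 1:3, drop = FALSE]     # rgb + alpha
  if (dim(img)[3] == 1L) img <- array(img, c(d[1], d[2], 3L))
  if (dim(img)[3] != 3L)
    stop_input("image must have 1-4 channels, got %d", d[3])
  if (!all(is.finite(img))) stop_input("image contains non-finite values")
  if (min(img) < 0 || max(img) > 1)
    stop_input("image values must lie in [0, 1]")
  img
}

#' Write a saliency map as an 8-bit grayscale PNG
#'
#' The map is rescaled to `[0, 1]` and quantized to 8 bits; use
#' [write_saliency_matrix()] for a lossless export.
#'
#' @param sal Numeric matrix (or `saliency_map`).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_saliency_png <- function(sal, path) {
  m <- normalize01(as_saliency_matrix(sal))
  png::writePNG(m, path)
  invisible(path)
}

#' Write a saliency map as a whitespace-delimited text matrix
#'
#' Full-precision lossless dump, one image row per line.
#'
#' @inheritParams write_saliency_png
#' @export
write_saliency_matrix <- function(sal, path) {
  m <- as_saliency_matrix(sal)
  utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a text saliency matrix written by [write_saliency_matrix()]
#' @param path Input path.
#' @return Numeric matrix.
#' @export
read_saliency_matrix <- function(path) {
  if (!file.exists(path)) stop_input("saliency matrix not found: %s", path)
  as.matrix(utils::read.table(path, header = FALSE))
}

as_saliency_matrix <- function(sal) {
  if (inherits(sal, "saliency_map")) sal$values
  else assert_matrix(sal, "saliency map")
}
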