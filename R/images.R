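# Image convention used throughout the package: a numeric array of dimension
# (height, width, 3) holding 8-bit values 0..255 (stored as doubles). Pixel
# coordinates are 0-based (x = column, y = row) with the origin at the
# top-left, so pixel (x, y) is img[y + 1, x + 1, ]. Masks are (height, width)
# matrices of 0/1.

assert_image <- function(img, what = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    abort(what, " must be a (height, width, 3) array")
  invisible(img)
}

clip8 <- function(x) pmin(pmax(x, 0), 255)

#' Read / write an 8-bit RGB PNG image
#'
#' Images are represented as `(height, width, 3)` arrays of 0--255 values.
#' Grayscale PNGs are expanded to three channels; an alpha channel is dropped.
#'
#' @param path File path.
#' @return `read_image_png()`: the image array. `write_image_png()`: `path`,
#'   invisibly.
#' @export
read_image_png <- function(path) {
  if (!file.exists(path)) abort("image file not found: ", path)
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  round_half_up(x * 255)
}

#' @rdname read_image_png
#' @param img Image array.
#' @export
write_image_png <- function(img, path) {
  assert_image(img)
  png::writePNG(clip8(img) / 255, path)
  invisible(path)
}

#' Read / write a binary mask PNG (single channel, 0/255 on disk)
#'
#' @param path File path.
#' @return `read_mask_png()`: a 0/1 matrix. `write_mask_png()`: `path`,
#'   invisibly.
#' @export
read_mask_png <- function(path) {
  if (!file.exists(path)) abort("mask file not found: ", path)
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  (x >= 0.5) * 1
}

#' @rdname read_mask_png
#' @param mask 0/1 matrix.
#' @export
write_mask_png <- function(mask, path) {
  if (!is.matrix(mask)) abort("mask must be a matrix")
  png::writePNG((mask != 0) * 1, path)
  invisible(path)
}

# flatten an image to an (n_pixels x 3) matrix and back
image_to_pixmat <- function(img) {
  d <- dim(img)
  dim(img) <- c(d[1] * d[2], 3L)
  img
}

pixmat_to_image <- function(m, h, w) {
  dim(m) <- c(h, w, 3L)
  m
}

# sRGB (0..1) <-> CIELAB on (n x 3) matrices. D65 white point, standard sRGB
# companding; compiled single-pass implementation because the pipeline
# converts millions of pixels per run. Agreement with
# grDevices::convertColor is exercised in the test suite.
srgb_to_lab <- function(rgb) {
  out <- srgb_to_lab_cpp(rgb)
  colnames(out) <- c("L", "a", "b")
  out
}

lab_to_srgb <- function(lab) {
  lab_to_srgb_cpp(lab)
}
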