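# Image containers are plain base-R arrays: RGB as height x width x 3 doubles
# in [0, 1]; depth as an integer-valued matrix of millimetres.

assert_rgb <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] < 3L) {
    abort(sprintf("`%s` must be a height x width x 3 RGB array.", arg))
  }
  invisible(image)
}

#' Read an RGB image
#'
#' Reads a PNG or TIFF image into a height x width x 3 array of doubles in
#' \[0, 1\]. An alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric array with dimensions height x width x 3.
#' @export
read_rgb <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("Unsupported image format '%s' (PNG or TIFF expected): %s", ext, path))
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an RGB image as PNG
#'
#' @param image Height x width x 3 array in \[0, 1\].
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_rgb <- function(image, path) {
  assert_rgb(image)
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Read / write a 16-bit depth map
#'
#' Depth maps hold the sensor-to-surface distance in integer millimetres
#' (the consumer depth-camera convention) and are stored as single-channel
#' 16-bit TIFF so that values up to 65535 mm round-trip exactly.
#'
#' @param path Path to a `.tif`/`.tiff` file.
#' @return `read_depth()`: an integer-valued matrix of millimetres.
#' @export
read_depth <- function(path) {
  d <- tiff::readTIFF(path)
  if (length(dim(d)) == 3L) d <- d[, , 1]
  round(d * 65535)
}

#' @rdname read_depth
#' @param depth_mm Matrix of millimetre distances (0..65535).
#' @return `write_depth()`: `path`, invisibly.
#' @export
write_depth <- function(depth_mm, path) {
  if (!is.matrix(depth_mm)) abort("`depth_mm` must be a matrix of millimetres.")
  if (any(depth_mm < 0 | depth_mm > 65535)) {
    abort("Depth values must lie in [0, 65535] mm for 16-bit storage.")
  }
  tiff::writeTIFF(round(depth_mm) / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}
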