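# Raster readers and writers.
#
# Tissue images are (H, W, 3) numeric arrays with values in [0, 255];
# instance masks are integer matrices (0 = background, k > 0 = gland k).
# Images travel as PNG or TIFF; masks as 16-bit single-channel TIFF (or
# 8-bit PNG when labels fit), always lossless. JPEG masks are refused.

img_ext <- function(path) tolower(tools::file_ext(path))

#' Read an RGB tissue tile
#'
#' Reads a PNG or TIFF tile into an `(H, W, 3)` array scaled to `[0, 255]`.
#' Grayscale inputs are replicated to three channels; an alpha channel is
#' dropped with a warning.
#'
#' @param path file path (`.png`, `.tif`, `.tiff`).
#' @return numeric array `(H, W, 3)` in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  ext <- img_ext(path)
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stopf("unsupported image format '%s' for %s (PNG/TIFF supported)", ext, path))
  if (length(dim(x)) == 2) {
    x <- array(rep(x, 3), dim = c(dim(x), 3))
  } else if (dim(x)[3] == 4) {
    warning(sprintf("dropping alpha channel of %s", path))
    x <- x[, , 1:3, drop = FALSE]
  } else if (dim(x)[3] != 3) {
    stopf("format error: %s has %d channels", path, dim(x)[3])
  }
  x * 255
}

#' Write an RGB tissue tile as PNG or TIFF
#'
#' @param img numeric array `(H, W, 3)` in `[0, 255]`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  v <- pmin(pmax(round(img), 0), 255) / 255
  ext <- img_ext(path)
  switch(ext,
    png = png::writePNG(v, path),
    tif = ,
    tiff = tiff::writeTIFF(v, path, bits.per.sample = 8L, compression = "none"),
    stopf("unsupported image format '%s'", ext))
  invisible(path)
}

#' Read an instance annotation mask
#'
#' Integer-labelled raster where 0 is background and k > 0 is gland instance
#' k. Lossy formats (JPEG) are refused; multi-channel rasters are refused.
#'
#' @param path file path (`.png`, `.tif`, `.tiff`).
#' @return integer matrix of labels.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stopf("mask file not found: %s", path)
  ext <- img_ext(path)
  if (ext %in% c("jpg", "jpeg"))
    stopf("format error: %s is JPEG; lossy formats cannot carry label masks", path)
  if (ext == "png") {
    x <- png::readPNG(path, info = TRUE)
    bits <- attr(x, "info")$bit.depth
    if (is.null(bits)) bits <- 8
    scale <- 2^bits - 1
  } else if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(x, "bits.per.sample")
    if (is.null(bits)) bits <- 16
    scale <- 2^bits - 1
  } else {
    stopf("unsupported mask format '%s' for %s", ext, path)
  }
  if (length(dim(x)) > 2)
    stopf("format error: %s is multi-channel; masks must be single-channel", path)
  lab <- matrix(as.integer(round(as.numeric(x) * scale)), nrow(x), ncol(x))
  lab
}

#' Write an instance annotation mask
#'
#' TIFF output is 16-bit; PNG output is 8-bit and only allowed when the
#' maximum label fits in a byte.
#'
#' @param mask integer matrix of labels (>= 0).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (any(mask < 0)) stopf("mask labels must be >= 0")
  ext <- img_ext(path)
  if (ext %in% c("tif", "tiff")) {
    if (max(mask) > 65535) stopf("labels exceed 16-bit range")
    tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L, compression = "none")
  } else if (ext == "png") {
    if (max(mask) > 255)
      stopf("labels exceed 8-bit range; write %s as TIFF instead", path)
    png::writePNG(mask / 255, path)
  } else {
    stopf("unsupported mask format '%s'", ext)
  }
  invisible(path)
}

#' Write a binary mask as 8-bit PNG with values {0, 255}
#'
#' @param mask logical or 0/1 matrix.
#' @param path destination `.png` path.
#' @return `path`, invisibly.
#' @export
write_binary_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}
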