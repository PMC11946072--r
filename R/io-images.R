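#' Read a grayscale image as a normalized matrix
#'
#' Loads a PNG or TIFF image (8-bit or float), converts RGB(A) to
#' luminance, and rescales values to `[0, 1]`.
#'
#' @param path image file (`.png`, `.tif`, `.tiff`).
#' @return numeric matrix in `[0, 1]`.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG requires the 'png' package", call. = FALSE)
    }
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    }
    tiff::readTIFF(path)
  } else {
    stop(sprintf("unsupported image format '%s'", ext), call. = FALSE)
  }
  if (length(dim(img)) == 3) {
    img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  }
  rng <- range(img)
  if (rng[2] > rng[1]) {
    img <- (img - rng[1]) / (rng[2] - rng[1])
  }
  img
}

#' Write a normalized matrix as an 8-bit grayscale PNG
#'
#' @param img numeric matrix; values are clipped to `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("writing PNG requires the 'png' package", call. = FALSE)
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  png::writePNG(img, path)
  invisible(path)
}
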