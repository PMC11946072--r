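#' Record a camera speckle image from a Jones field
#'
#' The camera integrates total intensity without an analyzer:
#' `I = |ex|^2 + |ey|^2`.  Optionally applies Poisson shot noise at a given
#' photon budget and uniform quantization, then normalizes the image to
#' `[0, 1]` by its maximum (per-image normalization, as is standard for
#' learning pipelines on uncalibrated camera frames).
#'
#' @param field a [jones_field()].
#' @param noise photons at unit intensity for Poisson shot noise, or `NULL`
#'   for a noiseless detector.
#' @param read_noise detector read noise, standard deviation in
#'   photoelectrons (applied on the photon counts; requires `noise`).
#'   Because read noise is independent of the transmitted power, it is the
#'   dominant mechanism by which low-transmissivity (thick) media degrade
#'   recorded frames.
#' @param quantize bit depth for uniform quantization, or `NULL`.
#' @param seed integer seed for the noise draw (ignored when `noise` is
#'   `NULL`).
#' @param provenance optional named list stored alongside the image
#'   (medium seed, drift step, encoding mode, polarization).
#' @return an object of class `speckle_record` with fields `intensity`
#'   (matrix in `[0, 1]`, maximum exactly 1 unless identically zero) and
#'   `provenance`.
#' @export
record_speckle <- function(field, noise = NULL, quantize = NULL, seed = 1,
                           read_noise = 0, provenance = list()) {
  stopifnot(inherits(field, "jones_field"))
  intensity <- Mod(field$ex)^2 + Mod(field$ey)^2
  if (!is.null(noise)) {
    stopifnot(noise > 0, read_noise >= 0)
    intensity <- with_seed(seed, {
      counts <- rpois(length(intensity), intensity * noise)
      if (read_noise > 0) {
        counts <- pmax(counts + rnorm(length(counts), 0, read_noise), 0)
      }
      matrix(counts / noise, nrow(intensity), ncol(intensity))
    })
  }
  m <- max(intensity)
  if (m > 0) intensity <- intensity / m
  if (!is.null(quantize)) {
    stopifnot(quantize >= 1)
    levels <- 2^quantize - 1
    intensity <- round(intensity * levels) / levels
  }
  structure(
    list(intensity = intensity, provenance = provenance),
    class = "speckle_record"
  )
}

#' @export
print.speckle_record <- function(x, ...) {
  cat(sprintf(
    "<speckle_record> %dx%d, mean intensity %.4f\n",
    nrow(x$intensity), ncol(x$intensity), mean(x$intensity)
  ))
  invisible(x)
}

#' Speckle contrast
#'
#' Ratio of the standard deviation to the mean of intensity.  Fully
#' developed single-polarization speckle has unit contrast.
#'
#' @param intensity non-negative intensity matrix.
#' @return `sd(I) / mean(I)`.
#' @export
speckle_contrast <- function(intensity) {
  sd(intensity) / mean(intensity)
}
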