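#' Construct a phase target
#'
#' A phase target couples one or two normalized glyphs with the phase maps
#' \eqn{\delta_1(x,y)}, \eqn{\delta_2(x,y)} that the two orthogonal
#' polarization components of the input field carry.  In single mode the two
#' components carry the same image (\eqn{\delta_1 = \delta_2}); in dual mode
#' they carry independent images.
#'
#' @param glyph1 numeric matrix in `[0, 1]` (the first label image).
#' @param glyph2 optional second glyph of the same size; supplying it selects
#'   dual mode.
#' @param phase_scale scalar in `(0, 2*pi]` mapping glyph gray level to phase
#'   in radians.  The default `pi` gives maximal interferometric contrast for
#'   binary strokes while avoiding the 2*pi phase wrap that would alias
#'   full-intensity pixels back to zero phase.
#' @return an object of class `phase_target` with fields `glyph1`, `glyph2`,
#'   `delta1`, `delta2`, `mode` (`"single"` or `"dual"`) and `phase_scale`.
#' @export
#' @examples
#' tg <- phase_target(generate_glyph("digit-like", 32, 1))
#' tg$mode
phase_target <- function(glyph1, glyph2 = NULL, phase_scale = pi) {
  stopifnot(is.matrix(glyph1), is.numeric(glyph1))
  if (phase_scale <= 0 || phase_scale > 2 * pi) {
    stop("`phase_scale` must lie in (0, 2*pi]", call. = FALSE)
  }
  if (min(glyph1) < 0 || max(glyph1) > 1) {
    stop("`glyph1` must be normalized to [0, 1]", call. = FALSE)
  }
  mode <- "single"
  if (!is.null(glyph2)) {
    stopifnot(is.matrix(glyph2), all(dim(glyph2) == dim(glyph1)))
    if (min(glyph2) < 0 || max(glyph2) > 1) {
      stop("`glyph2` must be normalized to [0, 1]", call. = FALSE)
    }
    mode <- "dual"
  } else {
    glyph2 <- glyph1
  }
  structure(
    list(
      glyph1 = glyph1, glyph2 = glyph2,
      delta1 = phase_scale * glyph1, delta2 = phase_scale * glyph2,
      mode = mode, phase_scale = phase_scale
    ),
    class = "phase_target"
  )
}

#' @export
print.phase_target <- function(x, ...) {
  cat(sprintf(
    "<phase_target> %dx%d, mode=%s, phase_scale=%.4g rad\n",
    nrow(x$glyph1), ncol(x$glyph1), x$mode, x$phase_scale
  ))
  invisible(x)
}
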