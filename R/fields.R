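#' Construct a Jones field
#'
#' A vector optical field sampled on a square grid: two co-registered complex
#' amplitude maps for the x- and y-polarized components.
#'
#' @param ex,ey complex matrices of equal dimensions.
#' @return an object of class `jones_field` with fields `ex`, `ey`.
#' @export
jones_field <- function(ex, ey) {
  ex <- as_complex_matrix(ex); ey <- as_complex_matrix(ey)
  stopifnot(all(dim(ex) == dim(ey)))
  if (!all(is.finite(Re(ex)), is.finite(Im(ex)),
           is.finite(Re(ey)), is.finite(Im(ey)))) {
    stop("field components must be finite", call. = FALSE)
  }
  structure(list(ex = ex, ey = ey), class = "jones_field")
}

as_complex_matrix <- function(m) {
  stopifnot(is.matrix(m))
  if (!is.complex(m)) storage.mode(m) <- "complex"
  m
}

#' Total optical power of a Jones field
#'
#' @param field a [jones_field()].
#' @return `sum(|ex|^2 + |ey|^2)`.
#' @export
field_power <- function(field) {
  stopifnot(inherits(field, "jones_field"))
  sum(Mod(field$ex)^2) + sum(Mod(field$ey)^2)
}

#' @export
print.jones_field <- function(x, ...) {
  cat(sprintf(
    "<jones_field> %dx%d, power = %.6g\n",
    nrow(x$ex), ncol(x$ex), field_power(x)
  ))
  invisible(x)
}

#' Synthesize the input field carrying a phase target
#'
#' Builds the illumination field whose two orthogonal polarization components
#' carry the target's phase maps.  In vector mode the components are
#' unit-amplitude phase-only beams of equal power, expressed either directly
#' in the horizontal/vertical (HV) Jones frame or as a coherent superposition
#' of left- and right-circular basis vectors converted to the x/y frame via
#' `x = (L + R)/sqrt(2)`, `y = (L - R)/(i sqrt(2))`.  In scalar mode all the
#' power is in the x component, which carries `delta1` only.
#'
#' @param target a [phase_target()].
#' @param basis `"HV"` or `"circular"` (vector mode only).
#' @param polarization `"vector"` or `"scalar"`.
#' @return a [jones_field()] with total power `H * W` regardless of basis,
#'   polarization or target phases.
#' @export
synthesize_input_field <- function(target, basis = c("HV", "circular"),
                                   polarization = c("vector", "scalar")) {
  stopifnot(inherits(target, "phase_target"))
  basis <- match.arg(basis)
  polarization <- match.arg(polarization)
  p1 <- exp(1i * target$delta1)
  p2 <- exp(1i * target$delta2)
  if (polarization == "scalar") {
    return(jones_field(p1, matrix(0i, nrow(p1), ncol(p1))))
  }
  if (basis == "HV") {
    jones_field(p1 / sqrt(2), p2 / sqrt(2))
  } else {
    aL <- p1 / sqrt(2); aR <- p2 / sqrt(2)
    jones_field((aL + aR) / sqrt(2), (aL - aR) / (1i * sqrt(2)))
  }
}
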