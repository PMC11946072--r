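#' Encode phase maps into a two-carrier hologram
#'
#' Computes the real transmittance pattern that a phase-only spatial light
#' modulator would display to encode two phase images on orthogonal spatial
#' carriers,
#' \deqn{t(x,y) = 1 + \frac{\gamma}{2}\cos(2\pi f_0 x + \delta_1(x,y))
#'               + \frac{\gamma}{2}\cos(2\pi f_0 y + \delta_2(x,y)),}
#' with \eqn{x} the column coordinate and \eqn{y} the row coordinate on a
#' pixel lattice with origin at the top-left pixel (`x = (col-1)/W`,
#' `y = (row-1)/H`) and \eqn{f_0} in cycles per grid width.
#'
#' @param target a [phase_target()].
#' @param f0 carrier spatial frequency in cycles across the grid; must be at
#'   least 4 and small enough that the +1 orders stay separable
#'   (`f0 <= min(H, W) / 3`).
#' @param gamma modulation depth in `(0, 1]`.
#' @return an object of class `hologram` with fields `t` (the transmittance
#'   matrix, bounded by `1 - gamma` and `1 + gamma`), `f0` and `gamma`.
#' @export
encode_hologram <- function(target, f0, gamma = 1) {
  stopifnot(inherits(target, "phase_target"))
  H <- nrow(target$delta1); W <- ncol(target$delta1)
  if (f0 < 4) {
    stop("carrier frequency `f0` must be at least 4 cycles across the grid",
         call. = FALSE)
  }
  if (3 * f0 / 2 > min(H, W) / 2) {
    stop("carrier `f0` too high for this grid: diffraction orders overlap",
         call. = FALSE)
  }
  if (gamma <= 0 || gamma > 1) {
    stop("`gamma` must lie in (0, 1]", call. = FALSE)
  }
  x <- matrix((seq_len(W) - 1) / W, H, W, byrow = TRUE)
  y <- matrix((seq_len(H) - 1) / H, H, W)
  t_ <- 1 + gamma / 2 * cos(2 * pi * f0 * x + target$delta1) +
    gamma / 2 * cos(2 * pi * f0 * y + target$delta2)
  structure(list(t = t_, f0 = f0, gamma = gamma), class = "hologram")
}

#' Demodulate a two-carrier hologram
#'
#' Idealized model of the 4f spatial-filtering path: for each axis the +1
#' diffraction order is shifted to baseband and isolated with a
#' Gaussian-edged low-pass mask of radius `f0/2`, and the argument of the
#' resulting analytic signal recovers the encoded phase map up to a global
#' constant.
#'
#' @param holo a [encode_hologram()] result.
#' @return a list with matrices `delta1`, `delta2` (phases in
#'   \eqn{(-\pi, \pi]}) and `amplitude1`, `amplitude2` (magnitudes of the
#'   analytic signals, nominally `gamma/4`).
#' @export
demodulate_hologram <- function(holo) {
  stopifnot(inherits(holo, "hologram"))
  t_ <- holo$t; f0 <- holo$f0
  H <- nrow(t_); W <- ncol(t_)
  if (3 * f0 / 2 > min(H, W) / 2) {
    stop("diffraction orders overlap: hologram cannot be demodulated",
         call. = FALSE)
  }
  x <- matrix((seq_len(W) - 1) / W, H, W, byrow = TRUE)
  y <- matrix((seq_len(H) - 1) / H, H, W)
  # the unit bias of the transmittance is known exactly; removing it before
  # shifting eliminates the strong zero-order term and lets the mask edge
  # roll off gently without zero-order leakage
  tc <- t_ - 1
  a1 <- lowpass_filter(tc * exp(-2i * pi * f0 * x), f0 / 2)
  a2 <- lowpass_filter(tc * exp(-2i * pi * f0 * y), f0 / 2)
  if (max(Mod(a1)) < 1e-9 || max(Mod(a2)) < 1e-9) {
    stop("no carrier signal to demodulate (zero modulation depth?)",
         call. = FALSE)
  }
  list(
    delta1 = Arg(a1), delta2 = Arg(a2),
    amplitude1 = Mod(a1), amplitude2 = Mod(a2)
  )
}

# radially symmetric Gaussian-edged low-pass mask of the given radius, in
# cycles per grid width; edge width radius/2, hard-zeroed beyond two edge
# widths so neighbouring diffraction orders are excluded exactly
lowpass_filter <- function(z, radius) {
  H <- nrow(z); W <- ncol(z)
  fy <- fft_freqs(H); fx <- fft_freqs(W)
  r <- sqrt(outer(fy^2, fx^2, `+`))
  edge <- radius / 2
  mask <- ifelse(r <= radius, 1,
                 ifelse(r <= radius + 2 * edge,
                        exp(-((r - radius)^2) / (2 * edge^2)), 0))
  fft(fft(z) * mask, inverse = TRUE) / (H * W)
}

# FFT bin frequencies in cycles per grid width for an n-point axis
fft_freqs <- function(n) {
  k <- seq_len(n) - 1
  ifelse(k <= n / 2, k, k - n)
}

#' Root-mean-square phase error up to a global offset
#'
#' Phases are compared on the circle: the optimal global constant offset is
#' removed (the circular mean of the phase difference) before computing the
#' RMS of the wrapped residuals.
#'
#' @param recovered,truth phase matrices in radians.
#' @return RMS residual phase error in radians.
#' @export
phase_rms_error <- function(recovered, truth) {
  stopifnot(all(dim(recovered) == dim(truth)))
  d <- exp(1i * (recovered - truth))
  offset <- Arg(sum(d))
  resid <- Arg(d * exp(-1i * offset))
  sqrt(mean(resid^2))
}
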