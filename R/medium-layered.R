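#' Sample a layered Jones-screen scattering medium
#'
#' Scalable physical realization of the vector transmission operator for
#' large grids: a stack of `n_layers` thin scattering screens separated by
#' free-space diffraction.  Each screen applies, per pixel, a unitary Jones
#' matrix composed of an isotropic random phase (scalar scattering) and a
#' birefringent retarder (polarization coupling) whose retardance scales
#' with the anisotropy `coupling`; after every screen the field diffracts
#' over `layer_spacing` pixels by the unitary angular-spectrum method
#' (evanescent components are zeroed).  The generating random fields are
#' spatially smooth Gaussian fields (correlation length `corr_length`),
#' giving the forward-peaked scattering characteristic of soft tissue and
#' keeping the scattered light inside the propagating band.
#'
#' More layers mean a thicker, more strongly scrambling medium; the
#' end-to-end action is linear in the input field, so the stack realizes the
#' same operator contract as a dense VTM (see [effective_vtm()]).
#'
#' @param grid side length or `c(H, W)`.
#' @param n_layers number of screens `L >= 1` (thickness proxy).
#' @param coupling kappa in `[0, 1]` scaling the retardance distribution
#'   (retardance s.d. `kappa * pi`); 0 gives purely scalar screens.
#' @param layer_spacing propagation distance after each screen, in pixels.
#' @param seed integer seed.
#' @param wavelength optical wavelength in pixels (sets the angular-spectrum
#'   dispersion and the evanescent cutoff).
#' @param corr_length correlation length of the screen random fields, px.
#' @param phase_strength standard deviation of each screen's isotropic
#'   random phase, radians.
#' @return an object of class `layered_medium`.
#' @export
sample_layered_medium <- function(grid, n_layers, coupling = 0.25,
                                  layer_spacing = 8, seed = 1,
                                  wavelength = 1.4, corr_length = 3,
                                  phase_strength = 2.5) {
  grid <- grid_dims(grid)
  stopifnot(
    n_layers >= 1, coupling >= 0, coupling <= 1,
    layer_spacing >= 0, wavelength > 0, corr_length > 0, phase_strength >= 0
  )
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    lseed <- child_seed(seed, l)
    layers[[l]] <- with_seed(lseed, list(
      g_psi = smooth_gaussian_field(grid, corr_length),
      g_phi = smooth_gaussian_field(grid, corr_length),
      g_theta = smooth_gaussian_field(grid, corr_length)
    ))
  }
  structure(
    list(
      layers = layers, grid = grid, n_layers = as.integer(n_layers),
      coupling = coupling, layer_spacing = layer_spacing,
      wavelength = wavelength, corr_length = corr_length,
      phase_strength = phase_strength, seed = as.integer(seed)
    ),
    class = c("layered_medium", "scattering_medium")
  )
}

#' @export
print.layered_medium <- function(x, ...) {
  cat(sprintf(
    "<layered_medium> %dx%d grid, L=%d layers, kappa=%.3g, spacing=%.3g px, seed=%d\n",
    x$grid[1], x$grid[2], x$n_layers, x$coupling, x$layer_spacing, x$seed
  ))
  invisible(x)
}

# standardized Gaussian random field with Gaussian autocorrelation of the
# given length, built by FFT filtering of white noise
smooth_gaussian_field <- function(grid, corr_length) {
  H <- grid[1]; W <- grid[2]
  z <- matrix(rnorm(H * W), H, W)
  fy <- fft_freqs(H) / H # cycles per pixel
  fx <- fft_freqs(W) / W
  k2 <- outer(fy^2, fx^2, `+`)
  filt <- exp(-2 * pi^2 * corr_length^2 * k2)
  f <- Re(fft(fft(z) * filt, inverse = TRUE)) / (H * W)
  (f - mean(f)) / sd(f)
}

# per-pixel Jones matrix of one screen: J = e^{i psi} R(-theta) D R(theta),
# D = diag(e^{i phi/2}, e^{-i phi/2})
screen_jones <- function(layer, coupling, phase_strength) {
  psi <- phase_strength * layer$g_psi
  phi <- coupling * pi * layer$g_phi
  theta <- pi * layer$g_theta
  iso <- exp(1i * psi)
  c2 <- cos(phi / 2); s2 <- sin(phi / 2)
  j11 <- iso * (c2 + 1i * s2 * cos(2 * theta))
  j22 <- iso * (c2 - 1i * s2 * cos(2 * theta))
  j12 <- iso * (1i * s2 * sin(2 * theta))
  list(j11 = j11, j12 = j12, j21 = j12, j22 = j22)
}

# unitary angular-spectrum diffraction over distance z (pixels); evanescent
# spatial frequencies are zeroed
angular_spectrum_step <- function(e, z, wavelength) {
  if (z == 0) {
    return(e)
  }
  H <- nrow(e); W <- ncol(e)
  fy <- fft_freqs(H) / H
  fx <- fft_freqs(W) / W
  k <- 2 * pi / wavelength
  k2 <- outer((2 * pi * fy)^2, (2 * pi * fx)^2, `+`)
  kz2 <- k^2 - k2
  transfer <- ifelse(kz2 > 0, exp(1i * sqrt(pmax(kz2, 0)) * z), 0i)
  fft(fft(e) * transfer, inverse = TRUE) / (H * W)
}

#' @export
propagate.layered_medium <- function(field, medium) {
  check_grid(field, medium)
  ex <- field$ex; ey <- field$ey
  for (layer in medium$layers) {
    j <- screen_jones(layer, medium$coupling, medium$phase_strength)
    nx <- j$j11 * ex + j$j12 * ey
    ny <- j$j21 * ex + j$j22 * ey
    ex <- angular_spectrum_step(nx, medium$layer_spacing, medium$wavelength)
    ey <- angular_spectrum_step(ny, medium$layer_spacing, medium$wavelength)
  }
  jones_field(ex, ey)
}

#' @export
drift_medium.layered_medium <- function(medium, rate, seed) {
  if (rate == 0) {
    return(medium)
  }
  a <- sqrt(1 - rate); b <- sqrt(rate)
  for (l in seq_along(medium$layers)) {
    lseed <- child_seed(seed, l)
    fresh <- with_seed(lseed, list(
      g_psi = smooth_gaussian_field(medium$grid, medium$corr_length),
      g_phi = smooth_gaussian_field(medium$grid, medium$corr_length),
      g_theta = smooth_gaussian_field(medium$grid, medium$corr_length)
    ))
    for (nm in names(fresh)) {
      medium$layers[[l]][[nm]] <- a * medium$layers[[l]][[nm]] + b * fresh[[nm]]
    }
  }
  medium$seed <- as.integer(seed)
  medium
}

#' Explicit dense operator of a layered medium
#'
#' Constructs the dense vector-transmission-matrix representation of a
#' layered medium by propagating all `2N` canonical basis fields, one per
#' input mode and polarization.  Serves as the oracle tying the scalable
#' layered realization to the explicit 2x2-block matrix form: propagation
#' through the returned operator reproduces layered propagation on arbitrary
#' fields to numerical precision.
#'
#' @param medium a `layered_medium` on a grid of at most `cap` pixels a side.
#' @param cap largest allowed side length (dense memory guard).
#' @return a `dense_vtm` whose blocks encode the layered medium exactly
#'   (`ballistic_amp = 0`; all structure lives in the blocks).
#' @export
effective_vtm <- function(medium, cap = 24) {
  stopifnot(inherits(medium, "layered_medium"))
  H <- medium$grid[1]; W <- medium$grid[2]
  if (H > cap || W > cap) {
    stop(sprintf("grid %dx%d too large for a dense representation (cap %d)",
                 H, W, cap), call. = FALSE)
  }
  n <- H * W
  t11 <- matrix(0i, n, n); t12 <- matrix(0i, n, n)
  t21 <- matrix(0i, n, n); t22 <- matrix(0i, n, n)
  zero <- matrix(0i, H, W)
  for (j in seq_len(n)) {
    basis <- zero; basis[j] <- 1 + 0i
    ox <- propagate(jones_field(basis, zero), medium)
    t11[, j] <- as.vector(ox$ex); t21[, j] <- as.vector(ox$ey)
    oy <- propagate(jones_field(zero, basis), medium)
    t12[, j] <- as.vector(oy$ex); t22[, j] <- as.vector(oy$ey)
  }
  structure(
    list(
      d11 = t11, d12 = t12, d21 = t21, d22 = t22,
      grid = medium$grid, ballistic_amp = 0,
      coupling = medium$coupling, ballistic_fraction = 0,
      transmissivity = 1, seed = medium$seed
    ),
    class = c("dense_vtm", "scattering_medium")
  )
}
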