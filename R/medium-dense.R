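#' Sample a dense vector transmission matrix
#'
#' Draws the 2x2-block random linear operator that maps the flattened input
#' Jones field to the flattened output field,
#' \deqn{E_{out,x} = T_{11} E_{in,x} + T_{12} E_{in,y}, \quad
#'       E_{out,y} = T_{21} E_{in,x} + T_{22} E_{in,y}.}
#' The diffuse parts of the co-polarized blocks have i.i.d. circular complex
#' Gaussian entries of variance `eta * (1 - kappa) * (1 - beta) / N`, the
#' cross-polarized blocks variance `eta * kappa * (1 - beta) / N`
#' (`N = H * W` modes), and a ballistic term `sqrt(eta * beta) * I` is added
#' to the co-polarized blocks.  With `kappa = 0` the cross blocks are exactly
#' zero: the isotropic (ground-glass) limit in which the two polarization
#' components propagate independently.
#'
#' @param grid side length of the square grid, or `c(H, W)`.
#' @param coupling kappa in `[0, 1]`: fraction of diffuse power routed
#'   through the cross-polarization blocks (0 = isotropic ground glass;
#'   the 0.25 default models the partial depolarization of mm-scale soft
#'   tissue; 0.5 mixes the components completely).
#' @param ballistic_fraction beta in `[0, 1]`: fraction of transmitted power
#'   that traverses the medium unscattered.
#' @param transmissivity eta in `(0, 1]`: expected ratio of output to input
#'   power over the random ensemble.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param dense_cap largest allowed side length (guards against the O(N^2)
#'   memory of the dense representation; use a layered medium beyond it).
#' @return an object of class `dense_vtm`.
#' @export
sample_dense_vtm <- function(grid, coupling = 0.25, ballistic_fraction = 0,
                             transmissivity = 1, seed = 1, dense_cap = 48) {
  grid <- grid_dims(grid)
  H <- grid[1]; W <- grid[2]
  if (H > dense_cap || W > dense_cap) {
    stop(sprintf(
      "grid %dx%d exceeds the dense-mode cap (%d): use sample_layered_medium()",
      H, W, dense_cap
    ), call. = FALSE)
  }
  stopifnot(
    coupling >= 0, coupling <= 1,
    ballistic_fraction >= 0, ballistic_fraction <= 1,
    transmissivity > 0, transmissivity <= 1
  )
  n <- H * W
  v_co <- transmissivity * (1 - coupling) * (1 - ballistic_fraction) / n
  v_cross <- transmissivity * coupling * (1 - ballistic_fraction) / n
  blocks <- with_seed(seed, {
    d11 <- gaussian_block(n, v_co)
    d22 <- gaussian_block(n, v_co)
    if (coupling > 0) {
      list(d11 = d11, d12 = gaussian_block(n, v_cross),
           d21 = gaussian_block(n, v_cross), d22 = d22)
    } else {
      list(d11 = d11, d12 = NULL, d21 = NULL, d22 = d22)
    }
  })
  structure(
    c(blocks, list(
      grid = grid,
      ballistic_amp = sqrt(transmissivity * ballistic_fraction),
      coupling = coupling, ballistic_fraction = ballistic_fraction,
      transmissivity = transmissivity, seed = as.integer(seed)
    )),
    class = c("dense_vtm", "scattering_medium")
  )
}

# n x n complex matrix with i.i.d. circular Gaussian entries, E|t|^2 = v
gaussian_block <- function(n, v) {
  if (v == 0) {
    return(matrix(0i, n, n))
  }
  matrix(complex(
    real = rnorm(n * n, sd = sqrt(v / 2)),
    imaginary = rnorm(n * n, sd = sqrt(v / 2))
  ), n, n)
}

grid_dims <- function(grid) {
  grid <- as.integer(grid)
  if (length(grid) == 1L) grid <- c(grid, grid)
  stopifnot(length(grid) == 2L, all(grid >= 2L))
  grid
}

#' @export
print.dense_vtm <- function(x, ...) {
  cat(sprintf(
    "<dense_vtm> %dx%d grid (%d modes), kappa=%.3g, beta=%.3g, eta=%.3g, seed=%d\n",
    x$grid[1], x$grid[2], prod(x$grid), x$coupling, x$ballistic_fraction,
    x$transmissivity, x$seed
  ))
  invisible(x)
}

#' Propagate a Jones field through a scattering medium
#'
#' Applies the medium's linear transmission operator to the field: matrix
#' action over flattened modes for a dense VTM; alternating per-pixel Jones
#' screens and angular-spectrum diffraction steps for a layered medium.
#' Propagation is linear in the input field in both modes.
#'
#' @param field a [jones_field()] whose grid matches the medium's.
#' @param medium a `dense_vtm` or `layered_medium`.
#' @return the output [jones_field()].
#' @export
propagate <- function(field, medium) {
  stopifnot(inherits(field, "jones_field"))
  UseMethod("propagate", medium)
}

#' @export
propagate.dense_vtm <- function(field, medium) {
  check_grid(field, medium)
  H <- medium$grid[1]; W <- medium$grid[2]
  out <- propagate_modes(
    matrix(as.vector(field$ex), ncol = 1),
    matrix(as.vector(field$ey), ncol = 1), medium
  )
  jones_field(matrix(out$ex, H, W), matrix(out$ey, H, W))
}

# batched dense propagation on flattened mode matrices (N x B)
propagate_modes <- function(ex, ey, medium) {
  ox <- medium$d11 %*% ex
  oy <- medium$d22 %*% ey
  if (!is.null(medium$d12)) ox <- ox + medium$d12 %*% ey
  if (!is.null(medium$d21)) oy <- oy + medium$d21 %*% ex
  if (medium$ballistic_amp > 0) {
    ox <- ox + medium$ballistic_amp * ex
    oy <- oy + medium$ballistic_amp * ey
  }
  list(ex = ox, ey = oy)
}

check_grid <- function(field, medium) {
  if (!all(dim(field$ex) == medium$grid)) {
    stop(sprintf(
      "field grid %dx%d does not match medium grid %dx%d",
      nrow(field$ex), ncol(field$ex), medium$grid[1], medium$grid[2]
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Advance a scattering medium by one drift step
#'
#' Models the slow temporal decorrelation of biological tissue (drying,
#' deformation) as a stationary autoregressive mixture: every random
#' component `M` of the medium is replaced by
#' `sqrt(1 - rate) * M + sqrt(rate) * M_fresh` where `M_fresh` is an
#' independent draw.  `rate = 0` leaves the medium untouched; `rate = 1`
#' yields a fresh independent medium; repeated application compounds the
#' decorrelation.
#'
#' @param medium a `dense_vtm` or `layered_medium`.
#' @param rate drift rate epsilon in `[0, 1]`.
#' @param seed integer seed for the fresh component.
#' @return a medium of the same class at the next time step.
#' @export
drift_medium <- function(medium, rate, seed) {
  stopifnot(rate >= 0, rate <= 1)
  UseMethod("drift_medium")
}

#' @export
drift_medium.dense_vtm <- function(medium, rate, seed) {
  if (rate == 0) {
    return(medium)
  }
  fresh <- sample_dense_vtm(
    medium$grid, medium$coupling, medium$ballistic_fraction,
    medium$transmissivity, seed = seed, dense_cap = max(medium$grid)
  )
  a <- sqrt(1 - rate); b <- sqrt(rate)
  for (nm in c("d11", "d12", "d21", "d22")) {
    if (!is.null(medium[[nm]])) {
      medium[[nm]] <- a * medium[[nm]] + b * fresh[[nm]]
    }
  }
  medium$seed <- as.integer(seed)
  medium
}
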