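#' Pearson correlation coefficient between two images
#'
#' Standard Pearson correlation over flattened pixels.  A constant image has
#' no defined correlation; the value is reported as 0 with a warning.
#'
#' @param a,b numeric matrices of equal dimensions.
#' @return scalar in `[-1, 1]`.
#' @export
pcc <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  if (sd(a) == 0 || sd(b) == 0) {
    warning("constant image: PCC undefined, reported as 0", call. = FALSE)
    return(0)
  }
  cor(as.vector(a), as.vector(b))
}

#' Structural similarity index between two images
#'
#' Windowed SSIM with the standard parameters: 11x11 Gaussian window with
#' sigma 1.5, stabilizers `C1 = (K1*L)^2`, `C2 = (K2*L)^2` with `K1 = 0.01`,
#' `K2 = 0.03`, averaged over all fully supported (valid) window positions.
#' Images smaller than the window fall back to global statistics with a
#' warning.
#'
#' @param a,b numeric matrices of equal dimensions.
#' @param L dynamic range of the data (1 for normalized images).
#' @return scalar SSIM in `[-1, 1]`.
#' @export
ssim <- function(a, b, L = 1) {
  stopifnot(all(dim(a) == dim(b)), L > 0)
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  win <- 11L
  if (nrow(a) < win || ncol(a) < win) {
    warning("image smaller than the SSIM window: using global statistics",
            call. = FALSE)
    mu_a <- mean(a); mu_b <- mean(b)
    va <- mean((a - mu_a)^2); vb <- mean((b - mu_b)^2)
    cab <- mean((a - mu_a) * (b - mu_b))
    return(((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
             ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2)))
  }
  g <- gaussian_window(win, 1.5)
  mu_a <- filter_valid(a, g); mu_b <- filter_valid(b, g)
  va <- filter_valid(a * a, g) - mu_a^2
  vb <- filter_valid(b * b, g) - mu_b^2
  cab <- filter_valid(a * b, g) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  mean(s)
}

gaussian_window <- function(n, sigma) {
  x <- seq_len(n) - (n + 1) / 2
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

# separable 'valid' correlation with a 1-D window applied to rows then
# columns: G_row %*% X %*% t(G_col) via band matrices
filter_valid <- function(x, w) {
  n <- length(w)
  H <- nrow(x); W <- ncol(x)
  gr <- band_matrix(H, w)
  gc <- band_matrix(W, w)
  gr %*% x %*% t(gc)
}

band_matrix <- function(size, w) {
  n <- length(w)
  out <- matrix(0, size - n + 1, size)
  for (k in seq_len(n)) {
    out[cbind(seq_len(size - n + 1), seq_len(size - n + 1) + k - 1)] <- w[k]
  }
  out
}

#' Peak signal-to-noise ratio in decibels
#'
#' `10 * log10(MAX^2 / MSE)`; identical images (zero MSE) are reported at
#' the cap value so table aggregation stays finite.
#'
#' @param a,b numeric matrices of equal dimensions.
#' @param max_value declared peak value of the data (1 for normalized
#'   images).
#' @param cap value reported for zero error, dB.
#' @return PSNR in dB.
#' @export
psnr <- function(a, b, max_value = 1, cap = 100) {
  stopifnot(all(dim(a) == dim(b)), max_value > 0)
  mse <- mean((a - b)^2)
  if (mse == 0) {
    return(cap)
  }
  min(10 * log10(max_value^2 / mse), cap)
}
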