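#' Generate a procedural phase-target glyph
#'
#' Produces a normalized grayscale image used as a phase target and training
#' label.  The `"digit-like"` style emulates handwritten-digit strokes with a
#' few random smooth Bezier strokes of finite width; `"blobs"` and `"rings"`
#' give softer extended structures.  Glyphs are rasterized at up to 64 px
#' logical resolution and bilinearly upsampled to `size`, giving the
#' piecewise-smooth, stroke-like support typical of processed handwritten
#' digits.
#'
#' @param style one of `"digit-like"`, `"blobs"`, `"rings"`.
#' @param size output side length in pixels (square image, `size >= 16`).
#' @param seed integer seed; the generator is a pure function of
#'   `(style, size, seed)`.
#' @return a `size x size` numeric matrix with values in `[0, 1]` whose
#'   support (pixels above 0.1) covers roughly 5--40% of the image.
#' @export
#' @examples
#' g <- generate_glyph("digit-like", 64, seed = 1)
#' range(g)
generate_glyph <- function(style = c("digit-like", "blobs", "rings"),
                           size, seed) {
  style <- match.arg(style)
  if (!is.numeric(size) || size < 16) {
    stop("`size` must be at least 16 pixels", call. = FALSE)
  }
  size <- as.integer(size)
  res <- min(size, 64L)
  img <- with_seed(seed, {
    base <- switch(style,
      "digit-like" = glyph_strokes(res),
      "blobs"      = glyph_blobs(res),
      "rings"      = glyph_rings(res)
    )
    tune_support(base, res, style)
  })
  if (res != size) img <- resize_bilinear(img, size, size)
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

# pixel-centred unit coordinates of an n x n raster (x = column, y = row)
unit_grid <- function(n) {
  u <- (seq_len(n) - 0.5) / n
  list(x = matrix(u, n, n, byrow = TRUE), y = matrix(u, n, n))
}

# intensity = exp(-d^2 / 2 sigma^2) where d is the distance to the nearest
# point sampled along the stroke polyline; accumulated as a running minimum
stamp_polyline <- function(px, py, sigma, res, acc = NULL) {
  g <- unit_grid(res)
  d2 <- if (is.null(acc)) matrix(Inf, res, res) else acc
  for (k in seq_along(px)) {
    dk <- (g$x - px[k])^2 + (g$y - py[k])^2
    d2 <- pmin(d2, dk)
  }
  attr(d2, "sigma") <- sigma
  d2
}

glyph_strokes <- function(res, width = 0.035) {
  n_strokes <- sample(2:4, 1)
  d2 <- NULL
  for (s in seq_len(n_strokes)) {
    p <- matrix(runif(6, 0.18, 0.82), 3, 2)
    tt <- seq(0, 1, length.out = 80)
    bx <- (1 - tt)^2 * p[1, 1] + 2 * tt * (1 - tt) * p[2, 1] + tt^2 * p[3, 1]
    by <- (1 - tt)^2 * p[1, 2] + 2 * tt * (1 - tt) * p[2, 2] + tt^2 * p[3, 2]
    d2 <- stamp_polyline(bx, by, width, res, acc = d2)
  }
  exp(-d2 / (2 * width^2))
}

glyph_blobs <- function(res) {
  g <- unit_grid(res)
  n <- sample(3:6, 1)
  img <- matrix(0, res, res)
  for (k in seq_len(n)) {
    cx <- runif(1, 0.2, 0.8); cy <- runif(1, 0.2, 0.8)
    sg <- runif(1, 0.05, 0.10)
    amp <- runif(1, 0.6, 1)
    img <- img + amp * exp(-((g$x - cx)^2 + (g$y - cy)^2) / (2 * sg^2))
  }
  img / max(img)
}

glyph_rings <- function(res) {
  g <- unit_grid(res)
  n <- sample(1:2, 1)
  img <- matrix(0, res, res)
  for (k in seq_len(n)) {
    cx <- runif(1, 0.35, 0.65); cy <- runif(1, 0.35, 0.65)
    r0 <- runif(1, 0.15, 0.3)
    w <- runif(1, 0.02, 0.05)
    r <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
    img <- img + exp(-(r - r0)^2 / (2 * w^2))
  }
  img / max(img)
}

# rescale widths until the thresholded support lands in the contract band
tune_support <- function(img, res, style, lo = 0.05, hi = 0.40) {
  for (i in 1:6) {
    img <- img / max(img)
    frac <- mean(img > 0.1)
    if (frac >= lo && frac <= hi) break
    # dilate or erode the soft support by powering the profile
    img <- if (frac < lo) img^0.6 else img^1.6
  }
  img
}

#' Bilinear image resize
#'
#' @param img numeric matrix.
#' @param h,w output dimensions.
#' @return resized matrix.
#' @keywords internal
resize_bilinear <- function(img, h, w) {
  H <- nrow(img); W <- ncol(img)
  # map output pixel centres onto input pixel-centre coordinates
  ry <- (seq_len(h) - 0.5) * H / h + 0.5
  rx <- (seq_len(w) - 0.5) * W / w + 0.5
  y0 <- pmin(pmax(floor(ry), 1), H); y1 <- pmin(y0 + 1, H)
  x0 <- pmin(pmax(floor(rx), 1), W); x1 <- pmin(x0 + 1, W)
  fy <- pmin(pmax(ry - y0, 0), 1); fx <- pmin(pmax(rx - x0, 0), 1)
  a <- img[y0, x0, drop = FALSE]; b <- img[y0, x1, drop = FALSE]
  c_ <- img[y1, x0, drop = FALSE]; d <- img[y1, x1, drop = FALSE]
  wy <- matrix(fy, h, w); wx <- matrix(fx, h, w, byrow = TRUE)
  (1 - wy) * ((1 - wx) * a + wx * b) + wy * ((1 - wx) * c_ + wx * d)
}
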