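# Elementary differentiable operations used by the restoration network.
# Spatial tensors are R arrays in (H, W, N, C) layout (channel blocks
# outermost, so each channel is contiguous); token tensors are matrices
# with one row per token (token-major within sample) and K columns.

relu_fwd <- function(x) relu_fwd_cpp(x)

relu_bwd <- function(dy, y) relu_bwd_cpp(dy, y)

sigmoid_fwd <- function(x) 1 / (1 + exp(-x))

sigmoid_bwd <- function(dy, y) dy * y * (1 - y)

gelu_fwd <- function(x) gelu_fwd_cpp(x)

gelu_bwd <- function(dy, x) gelu_bwd_cpp(dy, x)

# 1x1 convolution: per-pixel linear map over channels
conv1x1_fwd <- function(x, w, b) {
  d <- dim(x)
  ym <- matrix(x, ncol = d[4]) %*% w
  ym <- sweep(ym, 2, b, `+`)
  array(ym, c(d[1], d[2], d[3], ncol(w)))
}

conv1x1_bwd <- function(x, w, dy) {
  d <- dim(x)
  xm <- matrix(x, ncol = d[4])
  dym <- matrix(dy, ncol = ncol(w))
  list(
    dx = array(dym %*% t(w), d),
    dw = t(xm) %*% dym,
    db = colSums(dym)
  )
}

concat_channels <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  cs <- vapply(parts, function(p) dim(p)[4], integer(1))
  array(unlist(parts, use.names = FALSE), c(d[1], d[2], d[3], sum(cs)))
}

split_channels <- function(x, sizes) {
  at <- 0L
  lapply(sizes, function(cp) {
    out <- x[, , , at + seq_len(cp), drop = FALSE]
    at <<- at + cp
    out
  })
}

# row-wise layer normalization over the K columns
layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(xhat * 1, 2, g, `*`)
  y <- sweep(y, 2, b, `+`)
  list(y = y, xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat; inv <- cache$inv
  dxhat <- sweep(dy, 2, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * inv
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

linear_fwd <- function(x, w, b) {
  y <- x %*% w
  y + rep(b, each = nrow(y))
}

linear_bwd <- function(x, w, dy) {
  list(dx = dy %*% t(w), dw = t(x) %*% dy, db = colSums(dy))
}
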