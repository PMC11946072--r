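# shared fixtures: all inputs are generated in code at test time

# complex field with spectrum truncated at `radius` cycles per pixel
bandlimited_field <- function(n, radius = 0.25, seed = 1) {
  withr::with_seed(seed, {
    z <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
    f <- fft_freqs_t(n) / n
    mask <- sqrt(outer(f^2, f^2, `+`)) <= radius
    fft(fft(z) * mask, inverse = TRUE) / (n * n)
  })
}

fft_freqs_t <- function(n) {
  k <- seq_len(n) - 1
  ifelse(k <= n / 2, k, k - n)
}

# smooth glyph in [0,1]: Gaussian-filtered white noise, min-max normalized
smooth_glyph <- function(n, sigma = 4, seed = 1) {
  withr::with_seed(seed, {
    z <- matrix(rnorm(n * n), n, n)
    f <- fft_freqs_t(n) / n
    filt <- exp(-2 * pi^2 * sigma^2 * outer(f^2, f^2, `+`))
    sm <- Re(fft(fft(z) * filt, inverse = TRUE)) / (n * n)
    (sm - min(sm)) / (max(sm) - min(sm))
  })
}

random_jones <- function(n, seed = 1, scale_y = 0.5) {
  ex <- bandlimited_field(n, seed = seed)
  jones_field(ex, scale_y * bandlimited_field(n, seed = seed + 1))
}

# reference SSIM: direct sliding-window double loop (valid windows only)
ssim_reference <- function(a, b, L = 1) {
  w1 <- outer(
    exp(-((1:11) - 6)^2 / (2 * 1.5^2)),
    exp(-((1:11) - 6)^2 / (2 * 1.5^2))
  )
  w1 <- w1 / sum(w1)
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  H <- nrow(a) - 10
  W <- ncol(a) - 10
  vals <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      wa <- a[i:(i + 10), j:(j + 10)]
      wb <- b[i:(i + 10), j:(j + 10)]
      mu_a <- sum(wa * w1); mu_b <- sum(wb * w1)
      va <- sum(wa^2 * w1) - mu_a^2
      vb <- sum(wb^2 * w1) - mu_b^2
      cab <- sum(wa * wb * w1) - mu_a * mu_b
      vals[i, j] <- ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
        ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
    }
  }
  mean(vals)
}

# tiny model configuration used across network tests
tiny_config <- function(variant = "trans_cnn", output_channels = 1L) {
  model_config(
    input_size = 16, patch_size = 8, embed_dim = 8, n_attention_layers = 1,
    n_heads = 2, cnn_base_channels = 2, output_channels = output_channels,
    variant = variant
  )
}
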