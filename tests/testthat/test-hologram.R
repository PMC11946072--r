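test_that("transmittance follows the two-carrier interference formula", {
  n <- 64
  zero <- phase_target(matrix(0, n, n), phase_scale = pi)
  # any phase_scale works since the glyph is zero; both carriers are 0 at
  # the origin pixel
  h <- encode_hologram(zero, f0 = 8, gamma = 1)
  expect_equal(h$t[1, 1], 2)
  # constant pi on the x-carrier flips its cosine at the origin
  tg_pi <- phase_target(matrix(1, n, n), phase_scale = pi)
  tg_pi$delta2 <- matrix(0, n, n) # delta1 = pi, delta2 = 0
  h2 <- encode_hologram(tg_pi, f0 = 8, gamma = 1)
  expect_equal(h2$t[1, 1], 1 - 1 / 2 + 1 / 2)
})

test_that("encoding matches an independent pointwise evaluation", {
  n <- 48
  g1 <- smooth_glyph(n, seed = 4)
  g2 <- smooth_glyph(n, seed = 5)
  tg <- phase_target(g1, g2)
  gamma <- 0.8
  f0 <- 8
  h <- encode_hologram(tg, f0, gamma)
  x <- matrix((seq_len(n) - 1) / n, n, n, byrow = TRUE)
  y <- matrix((seq_len(n) - 1) / n, n, n)
  direct <- 1 + gamma / 2 * cos(2 * pi * f0 * x + tg$delta1) +
    gamma / 2 * cos(2 * pi * f0 * y + tg$delta2)
  expect_lt(max(abs(h$t - direct)), 1e-12)
})

test_that("hologram bounds invariant holds for random targets", {
  for (gamma in c(0.3, 0.7, 1)) {
    tg <- phase_target(smooth_glyph(32, seed = gamma * 10))
    h <- encode_hologram(tg, f0 = 6, gamma = gamma)
    expect_gte(min(h$t), 1 - gamma - 1e-12)
    expect_lte(max(h$t), 1 + gamma + 1e-12)
  }
})

test_that("encoding rejects carriers that cannot be demodulated", {
  tg <- phase_target(smooth_glyph(32))
  expect_error(encode_hologram(tg, f0 = 2), "at least 4")
  expect_error(encode_hologram(tg, f0 = 15), "overlap")
  expect_error(encode_hologram(tg, f0 = 8, gamma = 0), "gamma")
})

test_that("constant phases are recovered exactly up to a global offset", {
  n <- 64
  tg <- phase_target(matrix(1, n, n), phase_scale = 1.0)
  tg$delta2 <- matrix(2.0, n, n)
  h <- encode_hologram(tg, f0 = 8, gamma = 1)
  rec <- demodulate_hologram(h)
  expect_lt(phase_rms_error(rec$delta1, tg$delta1), 1e-6)
  expect_lt(phase_rms_error(rec$delta2, tg$delta2), 1e-6)
})

test_that("smooth random glyph pairs round-trip below 0.05 rad RMS", {
  n <- 128
  tg <- phase_target(smooth_glyph(n, sigma = 4, seed = 2),
                     smooth_glyph(n, sigma = 4, seed = 3))
  h <- encode_hologram(tg, f0 = 16, gamma = 1)
  rec <- demodulate_hologram(h)
  expect_lt(phase_rms_error(rec$delta1, tg$delta1), 0.05)
  expect_lt(phase_rms_error(rec$delta2, tg$delta2), 0.05)
})

test_that("a zero-modulation hologram cannot be demodulated", {
  h <- structure(list(t = matrix(1, 64, 64), f0 = 8, gamma = 0),
                 class = "hologram")
  expect_error(demodulate_hologram(h), "no carrier")
})
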