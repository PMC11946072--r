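test_that("glyph generation is deterministic, normalized and supported", {
  for (style in c("digit-like", "blobs", "rings")) {
    g1 <- generate_glyph(style, 64, seed = 1)
    g2 <- generate_glyph(style, 64, seed = 1)
    expect_identical(g1, g2)
    expect_gte(min(g1), 0)
    expect_lte(max(g1), 1)
    frac <- mean(g1 > 0.1)
    expect_gte(frac, 0.05)
    expect_lte(frac, 0.40)
    expect_false(identical(g1, generate_glyph(style, 64, seed = 2)))
  }
})

test_that("blobs support fraction matches the direct count contract", {
  g <- generate_glyph("blobs", 32, seed = 7)
  frac <- sum(g > 0.1) / length(g)
  expect_gte(frac, 0.05)
  expect_lte(frac, 0.40)
})

test_that("glyph generation rejects unsupported input", {
  expect_error(generate_glyph("digit-like", 8, seed = 1), "at least 16")
  expect_error(generate_glyph("squiggles", 32, seed = 1))
})

test_that("glyphs upsample smoothly to larger grids", {
  g <- generate_glyph("digit-like", 128, seed = 3)
  expect_equal(dim(g), c(128, 128))
  expect_gte(min(g), 0)
  expect_lte(max(g), 1)
})

test_that("phase targets scale glyphs into radians and track mode", {
  g <- generate_glyph("digit-like", 32, seed = 1)
  tg <- phase_target(g)
  expect_equal(tg$mode, "single")
  expect_equal(tg$delta1, pi * g)
  expect_identical(tg$delta1, tg$delta2)
  g2 <- generate_glyph("digit-like", 32, seed = 2)
  tg2 <- phase_target(g, g2, phase_scale = pi / 2)
  expect_equal(tg2$mode, "dual")
  expect_equal(tg2$delta2, pi / 2 * g2)
  expect_false(identical(tg2$delta1, tg2$delta2))
  expect_error(phase_target(g, phase_scale = 0), "phase_scale")
  expect_error(phase_target(g * 2), "normalized")
})
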