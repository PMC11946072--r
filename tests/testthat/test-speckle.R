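test_that("camera intensity is the analyzer-free total intensity", {
  n <- 16
  f <- random_jones(n, seed = 1)
  rec <- record_speckle(f)
  raw <- Mod(f$ex)^2 + Mod(f$ey)^2
  expect_equal(rec$intensity, raw / max(raw), tolerance = 1e-12)
  # total intensity = sum of the two single-polarization intensities
  fx <- jones_field(f$ex, matrix(0i, n, n))
  fy <- jones_field(matrix(0i, n, n), f$ey)
  ix <- Mod(fx$ex)^2 + Mod(fx$ey)^2
  iy <- Mod(fy$ex)^2 + Mod(fy$ey)^2
  expect_lt(max(abs(raw - (ix + iy))), 1e-12)
})

test_that("a uniform field records as a uniform unit image", {
  f <- jones_field(matrix(1 + 0i, 8, 8), matrix(0i, 8, 8))
  rec <- record_speckle(f)
  expect_true(all(rec$intensity == 1))
})

test_that("fully developed single-polarization speckle has unit contrast", {
  contrasts <- vapply(1:6, function(s) {
    m <- sample_dense_vtm(48, coupling = 0, ballistic_fraction = 0,
                          transmissivity = 1, seed = s)
    tg <- phase_target(generate_glyph("digit-like", 48, seed = s))
    f <- synthesize_input_field(tg, polarization = "scalar")
    speckle_contrast(Mod(propagate(f, m)$ex)^2)
  }, numeric(1))
  expect_gte(mean(contrasts), 0.9)
  expect_lte(mean(contrasts), 1.1)
})

test_that("shot noise and quantization are deterministic given the seed", {
  f <- random_jones(16, seed = 3)
  r1 <- record_speckle(f, noise = 1000, quantize = 8, seed = 42)
  r2 <- record_speckle(f, noise = 1000, quantize = 8, seed = 42)
  expect_identical(r1$intensity, r2$intensity)
  r3 <- record_speckle(f, noise = 1000, quantize = 8, seed = 43)
  expect_false(identical(r1$intensity, r3$intensity))
  # quantization produces at most 2^bits distinct levels
  expect_lte(length(unique(as.vector(r1$intensity))), 256)
})
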