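test_that("scalar mode puts all power in the x component", {
  tg <- phase_target(smooth_glyph(32, seed = 1), smooth_glyph(32, seed = 2))
  f <- synthesize_input_field(tg, polarization = "scalar")
  expect_true(all(Mod(f$ey) == 0))
  expect_equal(field_power(f), 32 * 32)
  # the scalar field carries delta1 only
  expect_lt(max(abs(Arg(f$ex) - tg$delta1)), 1e-12)
})

test_that("vector HV mode splits power equally with unit total", {
  n <- 32
  tg <- phase_target(matrix(0, n, n), phase_scale = pi)
  f <- synthesize_input_field(tg, "HV", "vector")
  expect_equal(max(abs(Mod(f$ex) - 1 / sqrt(2))), 0, tolerance = 1e-12)
  expect_equal(max(abs(Mod(f$ey) - 1 / sqrt(2))), 0, tolerance = 1e-12)
  expect_equal(field_power(f), n * n)
})

test_that("circular and HV bases agree up to a fixed unitary transform", {
  n <- 32
  phi <- 0.7
  tg <- phase_target(matrix(phi / pi, n, n), phase_scale = pi)
  fc <- synthesize_input_field(tg, "circular", "vector")
  fh <- synthesize_input_field(tg, "HV", "vector")
  # equal phases: circular superposition collapses onto x with phase phi
  expect_lt(max(Mod(fc$ex - exp(1i * phi))), 1e-12)
  expect_lt(max(Mod(fc$ey)), 1e-12)
  expect_equal(field_power(fc), field_power(fh), tolerance = 1e-12)
})

test_that("total power is invariant to basis, mode and target phases", {
  n <- 24
  for (seed in 1:5) {
    tg <- phase_target(smooth_glyph(n, seed = seed),
                       smooth_glyph(n, seed = seed + 50))
    for (basis in c("HV", "circular")) {
      for (pol in c("vector", "scalar")) {
        f <- synthesize_input_field(tg, basis, pol)
        expect_equal(field_power(f), n * n, tolerance = 1e-10)
      }
    }
  }
})

test_that("jones fields validate their inputs", {
  expect_error(jones_field(matrix(0i, 4, 4), matrix(0i, 5, 5)))
  expect_error(jones_field(matrix(NaN, 4, 4), matrix(0i, 4, 4)), "finite")
  expect_error(synthesize_input_field(phase_target(smooth_glyph(16)),
                                      basis = "diagonal"))
})
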