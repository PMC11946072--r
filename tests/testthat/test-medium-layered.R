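test_that("a single scalar screen with no spacing only changes phase", {
  m <- sample_layered_medium(32, n_layers = 1, coupling = 0,
                             layer_spacing = 0, seed = 1)
  f <- random_jones(32, seed = 2)
  out <- propagate(f, m)
  expect_lt(max(abs(Mod(out$ex) - Mod(f$ex))), 1e-12)
  expect_lt(max(abs(Mod(out$ey) - Mod(f$ey))), 1e-12)
})

test_that("layered media conserve power for bandlimited inputs", {
  f <- jones_field(bandlimited_field(64, seed = 3),
                   0.5i * bandlimited_field(64, seed = 4))
  for (L in c(2, 4, 8)) {
    m <- sample_layered_medium(64, n_layers = L, coupling = 0.5, seed = L)
    ratio <- field_power(propagate(f, m)) / field_power(f)
    expect_gte(ratio, 0.99)
    expect_lte(ratio, 1.0 + 1e-9)
  }
})

test_that("layered propagation is linear in the input field", {
  m <- sample_layered_medium(24, n_layers = 3, coupling = 0.5, seed = 5)
  f1 <- random_jones(24, seed = 6)
  f2 <- random_jones(24, seed = 7)
  a <- 1.1 + 0.2i
  b <- -0.3 + 0.9i
  lhs <- propagate(jones_field(a * f1$ex + b * f2$ex,
                               a * f1$ey + b * f2$ey), m)
  o1 <- propagate(f1, m)
  o2 <- propagate(f2, m)
  expect_lt(max(Mod(lhs$ex - (a * o1$ex + b * o2$ex)),
                Mod(lhs$ey - (a * o1$ey + b * o2$ey))), 1e-10)
})

test_that("the dense reconstruction reproduces layered propagation", {
  m <- sample_layered_medium(8, n_layers = 3, coupling = 0.5,
                             layer_spacing = 4, seed = 8)
  dv <- effective_vtm(m)
  for (seed in 1:5) {
    f <- random_jones(8, seed = 10 + seed)
    o1 <- propagate(f, m)
    o2 <- propagate(f, dv)
    expect_lt(max(Mod(o1$ex - o2$ex), Mod(o1$ey - o2$ey)), 1e-8)
  }
})

test_that("isotropic layered media never mix polarizations", {
  m <- sample_layered_medium(8, n_layers = 3, coupling = 0,
                             layer_spacing = 4, seed = 9)
  dv <- effective_vtm(m)
  expect_lt(max(Mod(dv$d12)), 1e-10)
  expect_lt(max(Mod(dv$d21)), 1e-10)
})

test_that("effective_vtm refuses grids too large for dense storage", {
  m <- sample_layered_medium(32, n_layers = 1, seed = 1)
  expect_error(effective_vtm(m), "too large")
})

test_that("more layers decorrelate the output from the input intensity", {
  cors <- vapply(c(1, 3, 6), function(L) {
    mean(vapply(1:10, function(s) {
      g <- generate_glyph("blobs", 32, seed = s + 100)
      fr <- fft_freqs_t(32) / 32
      mask <- sqrt(outer(fr^2, fr^2, `+`)) <= 0.25
      amp <- fft(fft(matrix(as.complex(g + 0.2), 32, 32)) * mask,
                 inverse = TRUE) / (32 * 32)
      fin <- jones_field(amp, amp / 2)
      m <- sample_layered_medium(32, n_layers = L, coupling = 0.5, seed = s)
      out <- propagate(fin, m)
      i0 <- Mod(fin$ex)^2 + Mod(fin$ey)^2
      cor(as.vector(Mod(out$ex)^2 + Mod(out$ey)^2), as.vector(i0))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(cors) < 0))
})

test_that("layered drift is the identity at rate 0 and decorrelates", {
  m <- sample_layered_medium(48, n_layers = 2, seed = 11)
  expect_identical(drift_medium(m, 0, seed = 5), m)
  m1 <- drift_medium(m, 0.5, seed = 5)
  expect_false(identical(m1$layers[[1]]$g_psi, m$layers[[1]]$g_psi))
  # OU mixture preserves the field scale (finite-size fluctuations allowed:
  # the 3 px correlation length leaves ~250 independent patches)
  expect_equal(sd(m1$layers[[1]]$g_psi), 1, tolerance = 0.3)
})
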