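test_that("the isotropic limit has exactly zero cross-polarization blocks", {
  m <- sample_dense_vtm(16, coupling = 0, seed = 1)
  expect_null(m$d12)
  expect_null(m$d21)
  tg <- phase_target(smooth_glyph(16, seed = 2))
  f <- synthesize_input_field(tg, polarization = "scalar")
  out <- propagate(f, m)
  expect_true(all(Mod(out$ey) == 0))
})

test_that("the ballistic-only limit is the identity operator", {
  m <- sample_dense_vtm(12, coupling = 0.5, ballistic_fraction = 1,
                        transmissivity = 1, seed = 3)
  f <- random_jones(12, seed = 4)
  out <- propagate(f, m)
  expect_lt(max(Mod(out$ex - f$ex), Mod(out$ey - f$ey)), 1e-12)
})

test_that("dense propagation is linear in the input field", {
  m <- sample_dense_vtm(16, coupling = 0.5, ballistic_fraction = 0.2,
                        seed = 5)
  f1 <- random_jones(16, seed = 6)
  f2 <- random_jones(16, seed = 8)
  a <- 0.3 - 1.2i
  b <- -0.5 + 0.4i
  comb <- jones_field(a * f1$ex + b * f2$ex, a * f1$ey + b * f2$ey)
  lhs <- propagate(comb, m)
  o1 <- propagate(f1, m)
  o2 <- propagate(f2, m)
  expect_lt(max(Mod(lhs$ex - (a * o1$ex + b * o2$ex)),
                Mod(lhs$ey - (a * o1$ey + b * o2$ey))), 1e-10)
})

test_that("ensemble output power matches eta times input power", {
  tg <- phase_target(smooth_glyph(16, seed = 9))
  f <- synthesize_input_field(tg, "HV", "vector")
  for (eta in c(1, 0.6)) {
    ratios <- vapply(1:200, function(s) {
      m <- sample_dense_vtm(16, coupling = 0.5, ballistic_fraction = 0,
                            transmissivity = eta, seed = s)
      field_power(propagate(f, m)) / field_power(f)
    }, numeric(1))
    expect_gte(mean(ratios), 0.9 * eta)
    expect_lte(mean(ratios), 1.1 * eta)
  }
})

test_that("grids beyond the dense cap point the caller to layered mode", {
  expect_error(sample_dense_vtm(64, seed = 1), "layered")
})

test_that("drift is the identity at rate 0 and a fresh medium at rate 1", {
  m <- sample_dense_vtm(12, coupling = 0.5, seed = 7)
  expect_identical(drift_medium(m, 0, seed = 99)$d11, m$d11)
  m1 <- drift_medium(m, 1, seed = 99)
  # rate-1 drift is statistically independent: correlation of entries ~ 0
  expect_lt(abs(cor(Re(as.vector(m1$d11)), Re(as.vector(m$d11)))), 0.05)
})

test_that("speckle correlation decays monotonically under repeated drift", {
  tg <- phase_target(generate_glyph("digit-like", 16, seed = 5))
  f <- synthesize_input_field(tg, "HV", "vector")
  rho <- vapply(1:10, function(r) {
    m <- sample_dense_vtm(16, coupling = 0.5, ballistic_fraction = 0.3,
                          transmissivity = 0.9, seed = r)
    i0 <- record_speckle(propagate(f, m))$intensity
    pccs <- numeric(6)
    mm <- m
    for (t in 1:6) {
      mm <- drift_medium(mm, 0.25, seed = child_seed(r, 100 + t))
      pccs[t] <- pcc(i0, record_speckle(propagate(f, mm))$intensity)
    }
    cor(seq_along(pccs), pccs, method = "spearman")
  }, numeric(1))
  expect_lt(mean(rho), -0.9)
})
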