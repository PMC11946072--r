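test_that("the thickness ladder degrades monotonically in its knobs", {
  lad <- thickness_ladder()
  expect_equal(nrow(lad), 4)
  expect_true(all(diff(lad$thickness_mm) > 0))
  expect_true(all(diff(lad$transmissivity) < 0))
  expect_true(all(diff(lad$drift_rate) > 0))
  expect_true(all(diff(lad$n_layers) > 0))
})

test_that("the dynamic preset emits one row per session and channel", {
  ex <- run_experiment("dynamic", "desk", seed = 2, n_samples = 48,
                       epochs = 1)
  expect_s3_class(ex, "speckle_experiment")
  expect_equal(sort(ex$table$session), paste0("T", 0:3))
  expect_true(all(c("pcc", "ssim", "psnr") %in% names(ex$table)))
  expect_s3_class(autoplot(ex), "ggplot")
  expect_identical(tidy(ex), ex$table)
})

test_that("the dual-phase preset reports both channels", {
  ex <- run_experiment("dual_phase", "desk", seed = 3, n_samples = 24,
                       epochs = 1)
  expect_equal(sort(ex$table$channel), c(1, 2))
})

test_that("scalar_vs_vector honours a combo subset", {
  combos <- tibble::tibble(polarization = c("vector", "scalar"),
                           variant = "trans_cnn")
  ex <- run_experiment("scalar_vs_vector", "desk", seed = 4,
                       n_samples = 24, epochs = 1, combos = combos)
  expect_equal(nrow(ex$table), 2)
  expect_setequal(ex$table$polarization, c("vector", "scalar"))
})

test_that("experiment presets run on 32x32 grids at desk scale", {
  ex <- run_experiment("dynamic", "desk", seed = 1, n_samples = 16,
                       epochs = 1)
  ds <- ex$reports$dynamic$per_image
  expect_equal(max(ds$epoch), 4)
})
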