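small_config <- function(...) {
  dataset_config(grid = 16, ...)
}

test_that("dataset generation is deterministic given the root seed", {
  cfg <- small_config()
  d1 <- generate_dataset(cfg, 10, seed = 7)
  d2 <- generate_dataset(cfg, 10, seed = 7)
  expect_identical(d1, d2)
  p1 <- withr::local_tempfile(fileext = ".rds")
  p2 <- withr::local_tempfile(fileext = ".rds")
  write_dataset(d1, p1)
  write_dataset(d2, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("drift epochs are recorded in provenance", {
  cfg <- small_config(drift = list(n_epochs = 4, rate = 0.3))
  ds <- generate_dataset(cfg, 100, seed = 3)
  expect_equal(length(unique(ds$provenance$medium_seed)), 4)
  expect_equal(as.vector(table(ds$provenance$epoch)), rep(25, 4))
})

test_that("within-epoch speckles correlate more than across epochs", {
  cfg <- small_config(drift = list(n_epochs = 4, rate = 0.3))
  ds <- generate_dataset(cfg, 80, seed = 5)
  e <- ds$provenance$epoch
  flat <- matrix(ds$speckle, ncol = ds$n)
  cm <- suppressWarnings(cor(flat))
  same <- outer(e, e, `==`) & upper.tri(cm)
  diff_ <- outer(e, e, `!=`) & upper.tri(cm)
  expect_gt(mean(cm[same]), mean(cm[diff_]))
})

test_that("dual targets with a scalar field are allowed but flagged", {
  cfg <- small_config(mode = "dual", polarization = "scalar")
  expect_warning(ds <- generate_dataset(cfg, 4, seed = 1), "delta1")
  expect_equal(dim(ds$label)[3], 2)
})

test_that("containers round-trip through disk and validate their schema", {
  ds <- generate_dataset(small_config(), 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".rds")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_identical(back$speckle, ds$speckle)
  expect_identical(back$config_json, ds$config_json)
  broken <- ds
  broken$label <- NULL
  expect_error(validate_dataset(broken), "label")
  expect_error(validate_dataset(list()), "container")
})

test_that("unknown configuration keys are rejected", {
  expect_error(dataset_config(medium = list(kappa = 1)), "unknown")
  expect_error(dataset_config(drift = list(speed = 2)), "unknown")
})
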