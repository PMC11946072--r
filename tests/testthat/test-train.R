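# lightweight container with the right schema for split bookkeeping tests
fake_dataset <- function(n, epochs = 1L) {
  per <- ceiling(n / epochs)
  structure(
    list(
      speckle = array(runif(4 * n), c(2, 2, n)),
      label = array(runif(4 * n), c(2, 2, 1, n)),
      provenance = tibble::tibble(
        sample = seq_len(n),
        epoch = sort(rep_len(seq_len(epochs), n))
      ),
      config_json = "{}", n = as.integer(n), grid = c(2L, 2L)
    ),
    class = "speckle_dataset"
  )
}

test_that("the 8:2 split is disjoint, exhaustive and exactly sized", {
  sp <- split_dataset(fake_dataset(10), 0.8, seed = 1)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:10)
  big <- split_dataset(fake_dataset(10000), 0.8, seed = 2)
  expect_length(big$train, 8000)
  expect_length(big$test, 2000)
})

test_that("splits are stratified across drift epochs", {
  ds <- fake_dataset(100, epochs = 4L)
  sp <- split_dataset(ds, 0.8, seed = 3)
  test_epochs <- ds$provenance$epoch[sp$test]
  expect_equal(as.vector(table(test_epochs)), rep(5, 4))
})

test_that("degenerate splits are refused", {
  expect_error(split_dataset(fake_dataset(1), 0.8, seed = 1), "small")
})

training_fixture <- function(n = 40, seed = 11) {
  cfg <- dataset_config(grid = 16)
  ds <- generate_dataset(cfg, n, seed = seed)
  mc <- model_config(input_size = 16, patch_size = 8, embed_dim = 8,
                     n_attention_layers = 1, n_heads = 2,
                     cnn_base_channels = 2)
  list(ds = ds, mc = mc)
}

test_that("one epoch of training decreases the loss and is reproducible", {
  fx <- training_fixture()
  tc <- train_config(epochs = 3, seed = 5, eval_every = 0, batch_size = 8)
  m1 <- train(build_model(fx$mc, seed = 2), fx$ds, tc)
  expect_lt(utils::tail(m1$history$train_loss, 1), m1$history$train_loss[1])
  m2 <- train(build_model(fx$mc, seed = 2), fx$ds, tc)
  expect_identical(m1$history$train_loss, m2$history$train_loss)
  expect_identical(m1$params, m2$params)
})

test_that("the capacity sanity check memorizes a small training set", {
  cfg <- dataset_config(grid = 16)
  ds <- generate_dataset(cfg, 12, seed = 31)
  mc <- model_config(input_size = 16, patch_size = 8, embed_dim = 16,
                     n_attention_layers = 1, n_heads = 2,
                     cnn_base_channels = 4)
  tc <- train_config(epochs = 200, seed = 7, eval_every = 0, batch_size = 5,
                     learning_rate = 2e-3)
  m <- train(build_model(mc, seed = 3), ds, tc,
             split = list(train = 1:10, test = 11:12))
  ev <- evaluate(m, ds, 1:10)
  expect_gt(ev$overall$pcc, 0.95)
})

test_that("training rejects label/output channel mismatches", {
  fx <- training_fixture(n = 10)
  dpir <- model_config(input_size = 16, patch_size = 8, embed_dim = 8,
                       n_attention_layers = 1, n_heads = 2,
                       cnn_base_channels = 2, output_channels = 2L)
  expect_error(train(build_model(dpir, seed = 1), fx$ds, train_config()),
               "channel")
})

test_that("evaluation reports grouped and per-channel summaries", {
  cfg <- dataset_config(grid = 16, mode = "dual",
                        drift = list(n_epochs = 2, rate = 0.5))
  ds <- generate_dataset(cfg, 16, seed = 13)
  mc <- model_config(input_size = 16, patch_size = 8, embed_dim = 8,
                     n_attention_layers = 1, n_heads = 2,
                     cnn_base_channels = 2, output_channels = 2L)
  m <- train(build_model(mc, seed = 1), ds,
             train_config(epochs = 1, eval_every = 0, batch_size = 8))
  rep_ <- evaluate(m, ds, seq_len(16), group = "epoch")
  expect_equal(nrow(rep_$summary), 2 * 2) # 2 epochs x 2 channels
  # the overall mean is the unweighted mean of the channel means
  ch_means <- dplyr::summarise(rep_$per_image, pcc = mean(pcc),
                               .by = "channel")
  expect_equal(mean(ch_means$pcc), rep_$overall$pcc, tolerance = 1e-12)
  expect_error(evaluate(m, ds, integer(0)))
})

test_that("tidiers expose history and summaries as tibbles", {
  fx <- training_fixture(n = 16)
  tc <- train_config(epochs = 2, seed = 5, eval_every = 1, batch_size = 8)
  m <- train(build_model(fx$mc, seed = 2), fx$ds, tc)
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("epoch", "train_loss", "test_pcc"))
  gl <- glance(m)
  expect_equal(gl$epochs_trained, 2L)
  expect_equal(gl$parameters, count_parameters(m))
  rp <- evaluate(m, fx$ds, m$split$test)
  expect_s3_class(tidy(rp), "tbl_df")
  expect_named(glance(rp),
               c("pcc", "ssim", "psnr", "n_images"))
  expect_s3_class(autoplot(m), "ggplot")
  expect_s3_class(autoplot(rp), "ggplot")
})
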