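test_that("configuration enforces the architectural divisibility rules", {
  expect_error(model_config(input_size = 30), "divisible")
  expect_error(model_config(input_size = 32, patch_size = 12), "divisible")
  expect_error(model_config(input_size = 64, patch_size = 32), "patch_size")
  expect_error(model_config(input_size = 32, embed_dim = 30, n_heads = 4),
               "n_heads")
  expect_error(model_config(input_size = 32, output_channels = 3),
               "output_channels")
})

test_that("forward preserves spatial size and the token count is (H/P)^2", {
  m <- build_model(model_config(input_size = 32, patch_size = 8,
                                embed_dim = 16, n_attention_layers = 1,
                                n_heads = 2, cnn_base_channels = 2), seed = 1)
  expect_equal(nrow(m$params$pos_emb), (32 / 8)^2)
  x <- array(runif(32 * 32 * 2), c(32, 32, 2))
  y <- forward(m, x)
  expect_equal(dim(y), c(32, 32, 2, 1))
  expect_true(all(y >= 0 & y <= 1))
})

test_that("initialization is deterministic given the seed", {
  cfg <- tiny_config()
  m1 <- build_model(cfg, seed = 9)
  m2 <- build_model(cfg, seed = 9)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(cfg, seed = 10)
  expect_false(identical(m1$params, m3$params))
})

test_that("distinct inputs give distinct outputs at initialization", {
  m <- build_model(tiny_config(), seed = 2)
  x1 <- array(runif(16 * 16), c(16, 16, 1))
  x2 <- array(runif(16 * 16), c(16, 16, 1))
  expect_gt(max(abs(forward(m, x1) - forward(m, x2))), 0)
})

test_that("batched forward equals concatenated single forwards", {
  m <- build_model(tiny_config(output_channels = 2L), seed = 3)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  yb <- forward(m, x)
  for (k in 1:3) {
    ys <- forward(m, x[, , k, drop = FALSE])
    expect_equal(yb[, , k, ], ys[, , 1, ], tolerance = 1e-12)
  }
})

test_that("parameter counts behave monotonically", {
  base <- build_model(tiny_config("cnn_baseline"), seed = 1)
  full <- build_model(tiny_config("trans_cnn"), seed = 1)
  expect_lt(count_parameters(base), count_parameters(full))
  expect_equal(count_parameters(build_model(tiny_config(), seed = 5)),
               count_parameters(full))
  wider <- model_config(input_size = 16, patch_size = 8, embed_dim = 16,
                        n_attention_layers = 1, n_heads = 2,
                        cnn_base_channels = 2)
  expect_gt(count_parameters(build_model(wider, seed = 1)),
            count_parameters(full))
})

test_that("analytic gradients match finite differences", {
  for (variant in c("trans_cnn", "cnn_baseline")) {
    m <- build_model(tiny_config(variant, output_channels = 2L), seed = 3)
    # small perturbation moves pre-activations off exact ReLU kinks, where
    # the subgradient and the finite difference legitimately disagree
    m$params <- lapply(m$params, function(v) {
      v + withr::with_seed(7, rnorm(length(v), sd = 0.05))
    })
    x <- withr::with_seed(1, array(runif(16 * 16 * 2), c(16, 16, 2)))
    dldy <- withr::with_seed(2, array(rnorm(16 * 16 * 2 * 2),
                                      c(16, 16, 2, 2)))
    fw <- forward(m, x, train = TRUE)
    grads <- polspeckle:::backward(m, fw$cache, dldy)
    lossfn <- function(mm) sum(forward(mm, x) * dldy)
    eps <- 1e-6
    worst <- 0
    withr::with_seed(11, {
      for (nm in names(m$params)) {
        np <- length(m$params[[nm]])
        for (i in unique(c(1, np, sample(np, min(2, np))))) {
          mp <- m
          mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
          mn <- m
          mn$params[[nm]][i] <- mn$params[[nm]][i] - eps
          num <- (lossfn(mp) - lossfn(mn)) / (2 * eps)
          rel <- abs(num - grads[[nm]][i]) /
            max(1e-4, abs(num) + abs(grads[[nm]][i]))
          worst <- max(worst, rel)
        }
      }
    })
    expect_lt(worst, 1e-3)
  }
})

test_that("positional information lives only in the embeddings", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 4)
  Tn <- (cfg$input_size / cfg$patch_size)^2
  N <- 2
  E <- withr::with_seed(5, matrix(rnorm(Tn * N * cfg$embed_dim),
                                  Tn * N, cfg$embed_dim))
  base <- polspeckle:::transformer_tokens_fwd(E, m$params, cfg)$y
  perm <- withr::with_seed(6, sample(Tn))
  rows <- c(perm, Tn + perm) # same permutation within each sample block
  permuted <- polspeckle:::transformer_tokens_fwd(E[rows, ], m$params, cfg)$y
  # un-permuting the output recovers the original tokens exactly
  unperm <- permuted
  unperm[rows, ] <- permuted
  expect_equal(unperm, base, tolerance = 1e-10)
})

test_that("checkpoints round-trip through disk", {
  m <- build_model(tiny_config(), seed = 6)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  x <- array(runif(16 * 16), c(16, 16, 1))
  expect_identical(forward(back, x), forward(m, x))
})

test_that("forward rejects mismatched input shapes", {
  m <- build_model(tiny_config(), seed = 1)
  expect_error(forward(m, array(0, c(32, 32, 1))), "expected")
})
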