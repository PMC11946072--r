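#' Training configuration
#'
#' @param split_ratio fraction of samples assigned to the training split
#'   (the acquisition protocol divides its speckle/label pairs 8:2).
#' @param loss `"l2"` (pixelwise squared error) or `"l1"`.
#' @param learning_rate Adam step size.
#' @param epochs passes over the training split.
#' @param batch_size minibatch size.
#' @param seed integer seed controlling the split, batch order and any
#'   stochastic initialization downstream.
#' @param eval_every evaluate mean test-split PCC every this many epochs
#'   (0 disables the per-epoch test metric; the final report is unaffected).
#' @param ema_decay exponential-moving-average decay for the evaluation
#'   weights (Polyak averaging).  The returned model carries the averaged
#'   parameters, which damp the step-to-step optimization noise of short
#'   runs; 0 disables averaging.
#' @return a list of class `train_config`.
#' @export
train_config <- function(split_ratio = 0.8, loss = c("l2", "l1"),
                         learning_rate = 1e-3, epochs = 30, batch_size = 16,
                         seed = 1, eval_every = 1, ema_decay = 0.97) {
  loss <- match.arg(loss)
  stopifnot(split_ratio > 0, split_ratio < 1, learning_rate > 0,
            epochs >= 1, batch_size >= 1, ema_decay >= 0, ema_decay < 1)
  structure(
    list(split_ratio = split_ratio, loss = loss,
         learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), seed = as.integer(seed),
         eval_every = as.integer(eval_every), ema_decay = ema_decay),
    class = "train_config"
  )
}

#' Split a dataset into train and test indices
#'
#' Shuffled, disjoint and exhaustive split at the given ratio, determined by
#' the seed before any training.  When the container records several drift
#' epochs the split is stratified so that every epoch contributes samples to
#' both subsets (required for evaluating generalization across medium
#' states).
#'
#' @param dataset a `speckle_dataset`.
#' @param ratio train fraction (default the 8:2 protocol).
#' @param seed integer seed.
#' @return a list with integer vectors `train` and `test`.
#' @export
split_dataset <- function(dataset, ratio = 0.8, seed = 1) {
  validate_dataset(dataset)
  stopifnot(ratio > 0, ratio < 1)
  n <- dataset$n
  epochs <- dataset$provenance$epoch
  test_idx <- with_seed(seed, {
    out <- integer(0)
    for (e in unique(epochs)) {
      idx <- which(epochs == e)
      n_test <- round(length(idx) * (1 - ratio))
      n_test <- max(1L, min(length(idx) - 1L, n_test))
      out <- c(out, sample(idx, n_test))
    }
    out
  })
  if (length(test_idx) == 0 || length(test_idx) >= n) {
    stop("dataset too small to produce non-empty train and test splits",
         call. = FALSE)
  }
  list(train = sort(setdiff(seq_len(n), test_idx)), test = sort(test_idx))
}

#' Train a restoration model
#'
#' Minimizes the configured pixelwise loss between the network output and
#' the normalized glyph labels over the training split with the Adam
#' optimizer, logging per-epoch training loss (and, optionally, mean
#' test-split PCC).  Fully reproducible: the split, batch order and updates
#' are pure functions of the configuration seed.
#'
#' @param model a [build_model()] result whose input size matches the
#'   dataset grid and whose output channels match the label channels.
#' @param dataset a `speckle_dataset`.
#' @param config a [train_config()].
#' @param split optional precomputed [split_dataset()] result.
#' @return the trained `restoration_model` with a `history` tibble
#'   (`epoch`, `train_loss`, `test_pcc`) and the `split` attached.  When
#'   `ema_decay > 0` the model's `params` are the Polyak-averaged
#'   evaluation weights and the raw final-step weights are kept in
#'   `raw_params`.
#' @export
train <- function(model, dataset, config = train_config(), split = NULL) {
  stopifnot(inherits(model, "restoration_model"),
            inherits(config, "train_config"))
  validate_dataset(dataset)
  cfg <- model$config
  if (dataset$grid[1] != cfg$input_size) {
    stop("dataset grid does not match the model input size", call. = FALSE)
  }
  n_ch <- dim(dataset$label)[3]
  if (n_ch != cfg$output_channels) {
    stop(sprintf(
      "model emits %d channel(s) but labels have %d: dual-phase ",
      cfg$output_channels, n_ch
    ), "restoration requires matching DPIR configuration", call. = FALSE)
  }
  if (is.null(split)) {
    split <- split_dataset(dataset, config$split_ratio, config$seed)
  }
  tr <- split$train
  te <- split$test
  p <- model$params
  mstate <- lapply(p, function(v) array(0, dim(v) %||% length(v)))
  vstate <- lapply(p, function(v) array(0, dim(v) %||% length(v)))
  ema <- if (config$ema_decay > 0) model$params else NULL
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  step <- 0
  history <- vector("list", config$epochs)
  H <- dataset$grid[1]
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(child_seed(config$seed, 5e6 + ep), sample(tr))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (bi in batches) {
      x <- dataset$speckle[, , bi, drop = FALSE]
      lab <- aperm(dataset$label[, , , bi, drop = FALSE], c(1, 2, 4, 3))
      fw <- forward(model, x, train = TRUE)
      resid <- fw$y - lab
      if (config$loss == "l2") {
        loss <- mean(resid^2)
        dy <- 2 * resid / length(resid)
      } else {
        loss <- mean(abs(resid))
        dy <- sign(resid) / length(resid)
      }
      if (!is.finite(loss)) {
        stop(sprintf(
          "training diverged at epoch %d (non-finite loss); reduce the ",
          ep
        ), "learning rate", call. = FALSE)
      }
      ep_loss <- ep_loss + loss * length(bi)
      grads <- backward(model, fw$cache, dy)
      step <- step + 1
      # short linear warmup guards the first updates against the large
      # initial error signal
      lr_t <- lr * min(1, step / 50)
      corr <- sqrt(1 - b2^step) / (1 - b1^step)
      for (nm in names(p)) {
        g <- grads[[nm]]
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g^2
        model$params[[nm]] <- model$params[[nm]] -
          lr_t * corr * mstate[[nm]] / (sqrt(vstate[[nm]]) + eps)
      }
      p <- model$params
      if (!is.null(ema)) {
        d <- config$ema_decay
        for (nm in names(p)) {
          ema[[nm]] <- d * ema[[nm]] + (1 - d) * p[[nm]]
        }
      }
    }
    test_pcc <- NA_real_
    if (config$eval_every > 0 && ep %% config$eval_every == 0) {
      test_pcc <- mean_test_pcc(model, dataset, te)
    }
    history[[ep]] <- tibble::tibble(
      epoch = ep, train_loss = ep_loss / length(tr), test_pcc = test_pcc
    )
  }
  if (!is.null(ema)) {
    model$raw_params <- model$params
    model$params <- ema
  }
  model$history <- dplyr::bind_rows(history)
  model$split <- split
  model$train_config <- config
  model
}

# mean per-image PCC of channel-averaged predictions on an index set
mean_test_pcc <- function(model, dataset, idx) {
  preds <- predict_batched(model, dataset$speckle[, , idx, drop = FALSE])
  n_ch <- dim(dataset$label)[3]
  mean(vapply(seq_along(idx), function(k) {
    mean(vapply(seq_len(n_ch), function(ch) {
      suppressWarnings(pcc(preds[, , ch, k], dataset$label[, , ch, idx[k]]))
    }, numeric(1)))
  }, numeric(1)))
}

# returns predictions in user-facing (H, W, C, n) order
predict_batched <- function(model, x, batch_size = 32) {
  H <- dim(x)[1]; n <- dim(x)[3]
  out <- array(0, c(H, dim(x)[2], model$config$output_channels, n))
  for (bi in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    xb <- x[, , bi, drop = FALSE]
    out[, , , bi] <- aperm(forward(model, xb), c(1, 2, 4, 3))
  }
  out
}

#' Restore images from speckle patterns
#'
#' @param object a trained `restoration_model`.
#' @param speckle array `(H, W, n)` of speckle images (or a single matrix).
#' @param ... unused.
#' @return array `(H, W, output_channels, n)` of restored images.
#' @export
predict.restoration_model <- function(object, speckle, ...) {
  if (is.matrix(speckle)) {
    dim(speckle) <- c(dim(speckle), 1L)
  }
  predict_batched(object, speckle)
}

#' Evaluate a restoration model with the three reference metrics
#'
#' Computes per-image (and per-channel, for dual-phase output) PCC, SSIM
#' and PSNR of the restored images against the glyph labels, plus grouped
#' summaries.
#'
#' @param model a trained `restoration_model`.
#' @param dataset a `speckle_dataset`.
#' @param indices samples to evaluate (typically the test split).
#' @param group optional provenance column to group summaries by
#'   (e.g. `"epoch"`).
#' @return an object of class `metric_report`: list with `per_image`
#'   (tibble: sample, channel, pcc, ssim, psnr, epoch), `summary` (means
#'   and standard deviations, one row per group and channel plus the
#'   overall row).
#' @export
evaluate <- function(model, dataset, indices, group = NULL) {
  stopifnot(length(indices) > 0)
  validate_dataset(dataset)
  preds <- predict_batched(model, dataset$speckle[, , indices, drop = FALSE])
  n_ch <- model$config$output_channels
  rows <- vector("list", length(indices) * n_ch)
  r <- 0
  for (k in seq_along(indices)) {
    i <- indices[k]
    for (ch in seq_len(n_ch)) {
      pred <- preds[, , ch, k]
      lab <- dataset$label[, , ch, i]
      r <- r + 1
      rows[[r]] <- tibble::tibble(
        sample = i, channel = ch,
        pcc = suppressWarnings(pcc(pred, lab)),
        ssim = ssim(pred, lab),
        psnr = psnr(pred, lab),
        epoch = dataset$provenance$epoch[i]
      )
    }
  }
  per_image <- dplyr::bind_rows(rows)
  summarise_metrics <- function(df) {
    dplyr::summarise(
      df,
      pcc = mean(.data$pcc), ssim = mean(.data$ssim), psnr = mean(.data$psnr),
      pcc_sd = sd(.data$pcc), n = dplyr::n(),
      .by = dplyr::any_of(c(group, "channel"))
    )
  }
  structure(
    list(
      per_image = per_image,
      summary = summarise_metrics(per_image),
      overall = dplyr::summarise(
        per_image,
        pcc = mean(.data$pcc), ssim = mean(.data$ssim), psnr = mean(.data$psnr)
      ),
      group = group
    ),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  print(x$summary)
  invisible(x)
}
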