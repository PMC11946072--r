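#' Tidy a trained restoration model
#'
#' Returns the per-epoch training log as a tibble.
#'
#' @param x a trained `restoration_model`.
#' @param ... unused.
#' @return tibble with columns `epoch`, `train_loss`, `test_pcc`.
#' @export
tidy.restoration_model <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(epoch = integer(), train_loss = numeric(),
                          test_pcc = numeric()))
  }
  x$history
}

#' One-row summary of a trained restoration model
#'
#' @param x a trained `restoration_model`.
#' @param ... unused.
#' @return tibble with `variant`, `parameters`, `epochs_trained`,
#'   `final_train_loss`, `final_test_pcc`.
#' @export
glance.restoration_model <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    variant = x$config$variant,
    parameters = count_parameters(x),
    epochs_trained = if (is.null(h)) 0L else nrow(h),
    final_train_loss = if (is.null(h)) NA_real_ else utils::tail(h$train_loss, 1),
    final_test_pcc = if (is.null(h)) {
      NA_real_
    } else {
      rev(h$test_pcc[!is.na(h$test_pcc)])[1] %||% NA_real_
    }
  )
}

#' Tidy a metric report
#'
#' @param x a [evaluate()] result.
#' @param ... unused.
#' @return the per-image metric tibble.
#' @export
tidy.metric_report <- function(x, ...) x$per_image

#' One-row summary of a metric report
#'
#' @param x a [evaluate()] result.
#' @param ... unused.
#' @return tibble with overall mean `pcc`, `ssim`, `psnr` and `n_images`.
#' @export
glance.metric_report <- function(x, ...) {
  dplyr::mutate(x$overall, n_images = nrow(x$per_image))
}

#' Tidy an experiment bundle
#'
#' @param x a [run_experiment()] result.
#' @param ... unused.
#' @return the experiment's group-level metric table.
#' @export
tidy.speckle_experiment <- function(x, ...) x$table

#' Plot the training curve of a restoration model
#'
#' @param object a trained `restoration_model`.
#' @param ... unused.
#' @return a ggplot object: training loss (and test PCC where logged)
#'   against epoch.
#' @export
autoplot.restoration_model <- function(object, ...) {
  h <- tidy(object)
  df <- tidyr::pivot_longer(h, c("train_loss", "test_pcc"),
                            names_to = "series", values_to = "value")
  df <- dplyr::filter(df, !is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = sprintf("training curve (%s)",
                                  object$config$variant)) +
    ggplot2::theme_minimal()
}

#' Plot per-image metric distributions of a report
#'
#' @param object a [evaluate()] result.
#' @param metric one of `"pcc"`, `"ssim"`, `"psnr"`.
#' @param ... unused.
#' @return a ggplot object: metric distribution per channel (and group).
#' @export
autoplot.metric_report <- function(object, metric = "pcc", ...) {
  df <- object$per_image
  df$channel <- factor(df$channel)
  ggplot2::ggplot(df, ggplot2::aes(.data$channel, .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(title = sprintf("per-image %s", toupper(metric))) +
    ggplot2::theme_minimal()
}

#' Plot an experiment's metric table
#'
#' @param object a [run_experiment()] result.
#' @param metric one of `"pcc"`, `"ssim"`, `"psnr"`.
#' @param ... unused.
#' @return a ggplot bar chart of the group means.
#' @export
autoplot.speckle_experiment <- function(object, metric = "pcc", ...) {
  tab <- object$table
  group_col <- switch(object$preset,
    dynamic = "session",
    thickness = "thickness_mm",
    scalar_vs_vector = "polarization",
    dual_phase = "channel"
  )
  tab$group <- interaction(tab[[group_col]],
                           tab[["variant"]] %||% "", drop = TRUE)
  ggplot2::ggplot(tab, ggplot2::aes(.data$group, .data[[metric]])) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::labs(x = NULL, y = toupper(metric),
                  title = sprintf("%s preset (seed %d)", object$preset,
                                  object$seed)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Montage of speckle, ground truth and reconstruction
#'
#' Draws a base-graphics panel of input speckle, label glyph(s) and network
#' restoration(s) for a handful of samples, mirroring the usual
#' qualitative-results layout.
#'
#' @param model a trained `restoration_model`.
#' @param dataset a `speckle_dataset`.
#' @param indices samples to display (at most 8).
#' @param path optional PNG path; when supplied the montage is written
#'   there (requires the `png` package) instead of drawn on the active
#'   device.
#' @return invisibly, the array of restored images.
#' @export
plot_montage <- function(model, dataset, indices, path = NULL) {
  indices <- utils::head(indices, 8)
  preds <- predict_batched(model, dataset$speckle[, , indices, drop = FALSE])
  n_ch <- model$config$output_channels
  ncol_ <- 1 + 2 * n_ch
  draw <- function() {
    op <- graphics::par(mfrow = c(length(indices), ncol_),
                        mar = c(0.2, 0.2, 1.2, 0.2))
    on.exit(graphics::par(op), add = TRUE)
    for (k in seq_along(indices)) {
      i <- indices[k]
      show_img(dataset$speckle[, , i], "speckle")
      for (ch in seq_len(n_ch)) {
        show_img(dataset$label[, , ch, i], sprintf("truth %d", ch))
        show_img(preds[, , ch, k], sprintf("restored %d", ch))
      }
    }
  }
  if (is.null(path)) {
    draw()
  } else {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("writing a montage PNG requires the 'png' package", call. = FALSE)
    }
    grDevices::png(path, width = 220 * ncol_, height = 220 * length(indices))
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
  }
  invisible(preds)
}

show_img <- function(m, title) {
  graphics::image(t(m)[, nrow(m):1], axes = FALSE, col = grDevices::gray.colors(128, 0, 1),
                  main = title, cex.main = 0.8, useRaster = TRUE)
}
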