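#' Thickness ladder for tissue-like media
#'
#' Four medium-degradation levels mirroring the 0.5/1.0/1.5/2.0 mm tissue
#' thickness series.  Thickness is emulated, not derived from absorption or
#' scattering coefficients: a thicker medium has lower transmissivity,
#' faster temporal decorrelation over the acquisition (multiple scattering
#' amplifies the tissue's micro-motion, so the speckle of a thick sample
#' drifts much faster than that of a thin one), and — in layered mode —
#' more screens.  The ballistic fraction is held fixed across the ladder:
#' its net effect on reconstruction is non-monotone (a stronger coherent
#' background also wastes ADC range after per-image normalization), so it
#' is not a degradation knob.  The drift rate is applied between the ten
#' acquisition blocks of a thickness dataset.  Only the monotone
#' degradation trend is meaningful.
#'
#' @return a tibble with columns `level`, `thickness_mm`,
#'   `ballistic_fraction`, `transmissivity`, `drift_rate`, `n_layers`.
#' @export
thickness_ladder <- function() {
  tibble::tibble(
    level = 1:4,
    thickness_mm = c(0.5, 1.0, 1.5, 2.0),
    ballistic_fraction = c(0.25, 0.25, 0.25, 0.25),
    transmissivity = c(0.9, 0.7, 0.5, 0.35),
    drift_rate = c(0, 0.015, 0.035, 0.09),
    n_layers = c(2L, 4L, 6L, 8L)
  )
}

# realistic desk camera shared by the experiment presets: finite photon
# budget, CMOS read noise and 8-bit quantization
desk_camera <- function() {
  list(photons = 150, read_noise = 3, bits = 8)
}

desk_model_config <- function(output_channels = 1L,
                              variant = "trans_cnn", grid = 32) {
  model_config(input_size = grid, output_channels = output_channels,
               variant = variant)
}

# one dataset -> train -> evaluate leg of an experiment preset
run_leg <- function(ds_config, n_samples, variant, output_channels,
                    epochs, seed, group = NULL, model_cfg = NULL) {
  ds <- generate_dataset(ds_config, n_samples, seed = child_seed(seed, 1))
  model <- build_model(
    model_cfg %||% desk_model_config(output_channels, variant,
                                     ds_config$grid),
    seed = child_seed(seed, 2)
  )
  tc <- train_config(epochs = epochs, seed = child_seed(seed, 3),
                     eval_every = 0)
  model <- train(model, ds, tc)
  report <- evaluate(model, ds, model$split$test, group = group)
  list(dataset = ds, model = model, report = report)
}

#' Run an experiment preset
#'
#' End-to-end execution of the four study designs on simulated data:
#' \describe{
#'   \item{`dynamic`}{one dataset acquired over four drift epochs
#'     (sessions T0..T3 of a slowly drying medium); a single model is
#'     trained jointly across epochs and evaluated per epoch.}
#'   \item{`scalar_vs_vector`}{scalar- and vector-illumination datasets of
#'     the same medium, each restored by the hybrid model and by the
#'     convolutional baseline (four arms).}
#'   \item{`thickness`}{one dataset per [thickness_ladder()] level, vector
#'     illumination, hybrid model.}
#'   \item{`dual_phase`}{a dual-target vector dataset restored by the
#'     two-channel (DPIR) head; metrics reported per channel.}
#' }
#'
#' At `scale = "desk"` datasets are 32 x 32 with 1,500 samples split 8:2
#' and a compact model; `n_samples` and `epochs` can be overridden to trade
#' precision for runtime.  `scale = "full"` uses 256 x 256 grids with a
#' layered medium and the full-size model (compute-intensive; intended for
#' workstation runs).
#'
#' @param preset one of `"dynamic"`, `"scalar_vs_vector"`, `"thickness"`,
#'   `"dual_phase"`.
#' @param scale `"desk"` or `"full"`.
#' @param seed root seed for the whole preset.
#' @param n_samples samples per dataset (default 1500 desk / 10000 full).
#' @param epochs training epochs (default 15 desk / 30 full).
#' @param combos for `scalar_vs_vector`: subset of the four arms to run,
#'   as a tibble with columns `polarization` and `variant`; `NULL` runs
#'   all four.
#' @return an object of class `speckle_experiment`: list with `preset`,
#'   `table` (tidy tibble of group means: one row per arm/epoch/level and
#'   channel with columns `pcc`, `ssim`, `psnr`), `reports` (named list of
#'   [evaluate()] results) and `seed`.
#' @export
run_experiment <- function(preset = c("dynamic", "scalar_vs_vector",
                                      "thickness", "dual_phase"),
                           scale = c("desk", "full"), seed = 1,
                           n_samples = NULL, epochs = NULL, combos = NULL) {
  preset <- match.arg(preset)
  scale <- match.arg(scale)
  grid <- if (scale == "desk") 32L else 256L
  med_type <- if (scale == "desk") "dense" else "layered"
  n_samples <- n_samples %||% if (scale == "desk") 1500L else 10000L
  epochs <- epochs %||% if (scale == "desk") 15L else 30L

  if (preset == "dynamic") {
    cfg <- dataset_config(
      grid = grid,
      medium = list(type = med_type),
      drift = list(n_epochs = 4, rate = 0.3),
      noise = desk_camera()
    )
    leg <- run_leg(cfg, n_samples, "trans_cnn", 1L, epochs,
                   child_seed(seed, 11), group = "epoch")
    tab <- leg$report$summary |>
      dplyr::mutate(session = paste0("T", .data$epoch - 1), .before = 1) |>
      dplyr::select(-"epoch")
    reports <- list(dynamic = leg$report)
  } else if (preset == "scalar_vs_vector") {
    if (is.null(combos)) {
      combos <- tidyr::expand_grid(
        polarization = c("scalar", "vector"),
        variant = c("trans_cnn", "cnn_baseline")
      )
    }
    # paired arms: identical glyphs, medium realization, initialization and
    # batch order across the four combinations -- only the arm knob differs
    legs <- purrr::pmap(combos, function(polarization, variant) {
      # the 1.0 mm acquisition-over-time condition: the medium drifts
      # across the ten acquisition blocks as the tissue dries
      cfg <- dataset_config(grid = grid, polarization = polarization,
                            medium = list(type = med_type,
                                          ballistic_fraction = 0.3,
                                          transmissivity = 0.7),
                            drift = list(n_epochs = 10, rate = 0.05),
                            noise = desk_camera())
      run_leg(cfg, n_samples, variant, 1L, epochs, child_seed(seed, 20))
    })
    tab <- purrr::map2_dfr(legs, seq_len(nrow(combos)), function(l, i) {
      dplyr::bind_cols(combos[i, ], l$report$summary)
    })
    reports <- stats::setNames(
      purrr::map(legs, "report"),
      paste(combos$polarization, combos$variant, sep = "_")
    )
  } else if (preset == "thickness") {
    ladder <- thickness_ladder()
    legs <- purrr::pmap(ladder, function(level, thickness_mm,
                                         ballistic_fraction, transmissivity,
                                         drift_rate, n_layers) {
      med <- if (med_type == "dense") {
        list(type = "dense", ballistic_fraction = ballistic_fraction,
             transmissivity = transmissivity)
      } else {
        list(type = "layered", n_layers = n_layers)
      }
      cfg <- dataset_config(
        grid = grid, medium = med,
        drift = list(continuous = drift_rate > 0, rate = drift_rate,
                     phase_sd = 2),
        noise = desk_camera()
      )
      # paired across ladder levels (same glyphs, medium seed, init)
      run_leg(cfg, n_samples, "trans_cnn", 1L, epochs, child_seed(seed, 40))
    })
    tab <- purrr::map2_dfr(legs, seq_len(4), function(l, i) {
      dplyr::bind_cols(ladder[i, c("level", "thickness_mm")],
                       l$report$summary)
    })
    reports <- stats::setNames(purrr::map(legs, "report"),
                               paste0(ladder$thickness_mm, "mm"))
  } else { # dual_phase
    cfg <- dataset_config(grid = grid, mode = "dual",
                          medium = list(type = med_type,
                                        ballistic_fraction = 0.3,
                                        transmissivity = 0.7),
                          noise = desk_camera())
    # the two-channel head shares one representation: double the width
    dpir_cfg <- if (scale == "desk") {
      model_config(input_size = grid, output_channels = 2L,
                   cnn_base_channels = 8L, embed_dim = 64L)
    } else {
      model_config(input_size = grid, output_channels = 2L)
    }
    leg <- run_leg(cfg, n_samples, "trans_cnn", 2L, epochs,
                   child_seed(seed, 51), model_cfg = dpir_cfg)
    tab <- leg$report$summary
    reports <- list(dual_phase = leg$report)
  }

  structure(
    list(preset = preset, scale = scale, table = tab, reports = reports,
         seed = as.integer(seed), n_samples = n_samples, epochs = epochs),
    class = "speckle_experiment"
  )
}

#' @export
print.speckle_experiment <- function(x, ...) {
  cat(sprintf("<speckle_experiment> preset=%s scale=%s seed=%d (n=%d, %d epochs)\n",
              x$preset, x$scale, x$seed, x$n_samples, x$epochs))
  print(x$table)
  invisible(x)
}
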