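#' Default dataset / simulation configuration
#'
#' Assembles the nested configuration consumed by [generate_dataset()] and
#' the command-line tools.  Defaults describe a tissue-like static medium:
#' anisotropy coupling 0.5, a moderate ballistic remnant, and phase targets
#' at scale pi.
#'
#' @param grid side length in pixels.
#' @param glyph_style passed to [generate_glyph()].
#' @param phase_scale passed to [phase_target()].
#' @param mode `"single"` (both polarization components carry the same
#'   image) or `"dual"` (independent images).
#' @param polarization `"vector"` or `"scalar"`.
#' @param basis `"HV"` or `"circular"`.
#' @param medium named list: `type` (`"dense"` or `"layered"`) plus the
#'   matching [sample_dense_vtm()] / [sample_layered_medium()] parameters.
#' @param drift named list with `n_epochs` (contiguous acquisition sessions
#'   sharing one medium state) and `rate` (drift rate applied between
#'   epochs).  Alternatively `continuous = TRUE` drifts the medium at
#'   every sample: an input-side random phase screen (amplitude
#'   `phase_sd` radians) advances by an Ornstein-Uhlenbeck step of mixing
#'   `rate` per sample, emulating the continuous optical-path-length
#'   drift of drying tissue; cheap even for dense media because the
#'   transmission blocks themselves stay fixed.
#' @param noise named list with `photons`, `read_noise` and `bits` as in
#'   [record_speckle()] (`noise`, `read_noise`, `quantize`).
#' @return a list of class `speckle_config`.
#' @export
dataset_config <- function(grid = 32,
                           glyph_style = "digit-like",
                           phase_scale = pi,
                           mode = c("single", "dual"),
                           polarization = c("vector", "scalar"),
                           basis = c("HV", "circular"),
                           medium = list(),
                           drift = list(),
                           noise = list()) {
  mode <- match.arg(mode)
  polarization <- match.arg(polarization)
  basis <- match.arg(basis)
  medium_defaults <- list(
    type = "dense", coupling = 0.25, ballistic_fraction = 0.3,
    transmissivity = 0.9, dense_cap = 48,
    n_layers = 4, layer_spacing = 8, wavelength = 1.4,
    corr_length = 3, phase_strength = 2.5
  )
  drift_defaults <- list(n_epochs = 1, rate = 0, continuous = FALSE,
                         phase_sd = 2.5)
  noise_defaults <- list(photons = NULL, read_noise = 0, bits = NULL)
  medium <- merge_config(medium_defaults, medium, "medium")
  drift <- merge_config(drift_defaults, drift, "drift")
  noise <- merge_config(noise_defaults, noise, "noise")
  structure(
    list(
      grid = as.integer(grid), glyph_style = glyph_style,
      phase_scale = phase_scale, mode = mode,
      polarization = polarization, basis = basis,
      medium = medium, drift = drift, noise = noise
    ),
    class = "speckle_config"
  )
}

merge_config <- function(defaults, user, section) {
  if (length(user) == 0) {
    return(defaults)
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop(sprintf("unknown %s config key(s): %s",
                 section, paste(unknown, collapse = ", ")), call. = FALSE)
  }
  defaults[names(user)] <- user
  defaults
}

sample_medium <- function(config, seed) {
  m <- config$medium
  if (m$type == "dense") {
    sample_dense_vtm(config$grid, m$coupling, m$ballistic_fraction,
                     m$transmissivity, seed = seed, dense_cap = m$dense_cap)
  } else if (m$type == "layered") {
    sample_layered_medium(config$grid, m$n_layers, m$coupling,
                          m$layer_spacing, seed = seed,
                          wavelength = m$wavelength,
                          corr_length = m$corr_length,
                          phase_strength = m$phase_strength)
  } else {
    stop(sprintf("unknown medium type '%s'", m$type), call. = FALSE)
  }
}

#' Generate a simulated speckle dataset
#'
#' End-to-end synthetic data protocol: for each sample a phase target is
#' drawn, encoded on the input vector (or scalar) field, propagated through
#' the scattering medium and recorded as a camera speckle image; the
#' normalized glyphs serve as the training labels.  Samples are divided into
#' contiguous drift epochs: within an epoch the medium is frozen, and
#' between epochs it advances by [drift_medium()] at the configured rate,
#' emulating acquisition sessions separated in time over a drying tissue.
#'
#' Every random draw derives its own child seed from `seed` by a fixed
#' counter scheme ([child_seed()]), so any single sample or epoch medium is
#' reproducible in isolation and the whole container is byte-identical
#' across runs.
#'
#' @param config a [dataset_config()].
#' @param n_samples number of speckle/label pairs.
#' @param seed root integer seed.
#' @return an object of class `speckle_dataset`: a named-array container
#'   with `speckle` (`H x W x n`, float in `[0, 1]`), `label`
#'   (`H x W x C x n`, `C = 1` for single mode, `2` for dual), `provenance`
#'   (a tibble with per-sample `sample`, `epoch`, `drift_step`,
#'   `medium_seed`, `glyph_seed1`, `glyph_seed2`, `mode`, `polarization`)
#'   and the JSON-serialized config.  Persist with [write_dataset()].
#' @export
generate_dataset <- function(config, n_samples, seed = 1) {
  stopifnot(inherits(config, "speckle_config"), n_samples >= 1)
  if (config$mode == "dual" && config$polarization == "scalar") {
    warning("dual targets with a scalar field: only delta1 is carried ",
            "by the field; glyph2 is retained as a label", call. = FALSE)
  }
  H <- config$grid; W <- config$grid
  continuous <- isTRUE(config$drift$continuous)
  n_epochs <- if (continuous) 1L else config$drift$n_epochs
  epoch_of <- sort(rep_len(seq_len(n_epochs), n_samples))
  n_channels <- if (config$mode == "dual") 2L else 1L

  speckle <- array(0, c(H, W, n_samples))
  label <- array(0, c(H, W, n_channels, n_samples))
  med_seeds <- integer(n_samples)

  medium <- NULL
  for (e in seq_len(n_epochs)) {
    eseed <- child_seed(seed, 1e6 + e)
    medium <- if (e == 1) {
      sample_medium(config, eseed)
    } else {
      drift_medium(medium, config$drift$rate, eseed)
    }
    idx <- which(epoch_of == e)
    med_seeds[idx] <- eseed
    targets <- lapply(idx, function(i) {
      g1 <- generate_glyph(config$glyph_style, config$grid,
                           child_seed(seed, 2e6 + 2 * i))
      g2 <- if (config$mode == "dual") {
        generate_glyph(config$glyph_style, config$grid,
                       child_seed(seed, 2e6 + 2 * i + 1))
      } else {
        NULL
      }
      phase_target(g1, g2, config$phase_scale)
    })
    fields <- lapply(targets, synthesize_input_field,
                     basis = config$basis, polarization = config$polarization)
    if (continuous && config$drift$rate > 0) {
      fields <- apply_phase_drift(fields, config$drift$rate,
                                  config$drift$phase_sd,
                                  child_seed(seed, 4e6))
    }
    outs <- propagate_batch(fields, medium)
    for (k in seq_along(idx)) {
      i <- idx[k]
      rec <- record_speckle(outs[[k]], noise = config$noise$photons,
                            read_noise = config$noise$read_noise,
                            quantize = config$noise$bits,
                            seed = child_seed(seed, 3e6 + i))
      speckle[, , i] <- rec$intensity
      label[, , 1, i] <- targets[[k]]$glyph1
      if (n_channels == 2L) label[, , 2, i] <- targets[[k]]$glyph2
    }
  }

  provenance <- tibble::tibble(
    sample = seq_len(n_samples),
    epoch = epoch_of,
    drift_step = if (continuous) seq_len(n_samples) - 1L else epoch_of - 1L,
    medium_seed = med_seeds,
    glyph_seed1 = child_seed(seed, 2e6 + 2 * seq_len(n_samples)),
    glyph_seed2 = ifelse(rep(n_channels == 2L, n_samples),
                         child_seed(seed, 2e6 + 2 * seq_len(n_samples) + 1),
                         NA_integer_),
    mode = config$mode,
    polarization = config$polarization
  )
  structure(
    list(
      speckle = speckle, label = label, provenance = provenance,
      config = config,
      config_json = as.character(jsonlite::toJSON(
        unclass(config), auto_unbox = TRUE, null = "null", digits = NA
      )),
      n = as.integer(n_samples), grid = c(H, W),
      root_seed = as.integer(seed)
    ),
    class = "speckle_dataset"
  )
}

# continuous tissue drift: a per-pixel random phase screen at the medium
# entrance advances by an OU step of mixing `rate` between consecutive
# samples; `phase_sd` sets its stationary amplitude in radians
apply_phase_drift <- function(fields, rate, phase_sd, seed) {
  n_px <- length(fields[[1]]$ex)
  h <- nrow(fields[[1]]$ex)
  with_seed(seed, {
    g <- rnorm(n_px)
    a <- sqrt(1 - rate); b <- sqrt(rate)
    lapply(fields, function(f) {
      g <<- a * g + b * rnorm(n_px)
      screen <- matrix(exp(1i * phase_sd * g), h)
      jones_field(f$ex * screen, f$ey * screen)
    })
  })
}

# propagate a list of fields, batching the dense-matrix action over modes
propagate_batch <- function(fields, medium) {
  if (inherits(medium, "dense_vtm")) {
    n <- length(fields)
    ex <- vapply(fields, function(f) as.vector(f$ex), complex(prod(medium$grid)))
    ey <- vapply(fields, function(f) as.vector(f$ey), complex(prod(medium$grid)))
    out <- propagate_modes(ex, ey, medium)
    lapply(seq_len(n), function(k) {
      jones_field(matrix(out$ex[, k], medium$grid[1], medium$grid[2]),
                  matrix(out$ey[, k], medium$grid[1], medium$grid[2]))
    })
  } else {
    lapply(fields, propagate, medium = medium)
  }
}

#' @export
print.speckle_dataset <- function(x, ...) {
  cat(sprintf(
    "<speckle_dataset> n=%d, grid %dx%d, %d label channel(s), %d epoch(s), %s/%s\n",
    x$n, x$grid[1], x$grid[2], dim(x$label)[3],
    max(x$provenance$epoch), x$config$mode, x$config$polarization
  ))
  invisible(x)
}

#' Write / read a dataset container
#'
#' The container is a single-file named-array archive (R serialization)
#' holding the arrays `speckle` (`H x W x n`) and `label`
#' (`H x W x C x n`), the per-sample `provenance` table and the
#' JSON-serialized configuration.
#'
#' @param dataset a `speckle_dataset`.
#' @param path file path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns
#'   the validated `speckle_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  validate_dataset(dataset)
  saveRDS(dataset, path, version = 3, compress = "gzip")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  dataset <- readRDS(path)
  validate_dataset(dataset)
  dataset
}

#' @rdname write_dataset
#' @export
validate_dataset <- function(dataset) {
  if (!inherits(dataset, "speckle_dataset")) {
    stop("not a speckle_dataset container", call. = FALSE)
  }
  for (nm in c("speckle", "label", "provenance", "config_json")) {
    if (is.null(dataset[[nm]])) {
      stop(sprintf("dataset container is missing the '%s' array", nm),
           call. = FALSE)
    }
  }
  if (length(dim(dataset$speckle)) != 3 || length(dim(dataset$label)) != 4) {
    stop("container arrays have wrong rank: expected speckle (H,W,n) and ",
         "label (H,W,C,n)", call. = FALSE)
  }
  if (dim(dataset$speckle)[3] != dim(dataset$label)[4]) {
    stop("speckle and label arrays disagree on sample count", call. = FALSE)
  }
  invisible(dataset)
}
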