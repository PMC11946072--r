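# polspeckle

Restoring images carried by light that has traversed biological tissue.

Coherent light passing through a scattering medium such as a slice of soft
tissue emerges as a speckle pattern — the image it carried appears
destroyed. When the illumination is a *vector* beam, its two orthogonal
polarization components carry one or two phase images and are additionally
coupled into one another by the tissue's anisotropy, while the tissue
itself slowly drifts as it dries. `polspeckle` is an R package for
studying learning-based restoration in exactly this regime, end to end and
without any laboratory data:

* **Simulation.** Propagation is modelled by the vector transmission
  matrix (VTM): the output Jones field is
  `(E'x, E'y) = ((T11, T12), (T21, T22)) (Ex, Ey)` over flattened grid
  modes. Two realizations are provided — an exact dense random-matrix
  form with anisotropy coupling `kappa`, ballistic fraction `beta` and
  transmissivity `eta`, and a scalable stack of birefringent Jones
  screens with angular-spectrum diffraction. Temporal tissue drift is an
  autoregressive decorrelation of the medium; the camera records
  analyzer-free total intensity.
* **Phase encoding.** Targets (procedural handwritten-digit-like glyphs)
  enter as phases on a two-carrier transmittance hologram
  `t(x,y) = 1 + (g/2) cos(2 pi f0 x + d1) + (g/2) cos(2 pi f0 y + d2)`,
  with an idealized Fourier order-selection demodulator as the optical
  reference path.
* **Restoration.** A hybrid network pairs a four-stage convolutional
  U-shaped encoder/decoder (local texture) with a patch-embedding
  self-attention encoder (global structure,
  `X_embed = X W_proj + pos_emb`), fuses the two at the bottleneck by
  elementwise product plus concatenation, and decodes to one (SPIR) or
  two (DPIR) phase-image channels. Forward pass, backpropagation and the
  Adam optimizer are implemented in the package over BLAS-backed C++
  kernels; a plain convolutional baseline provides the comparison arm.
* **Evaluation.** Pearson correlation (PCC), SSIM and PSNR, with
  experiment presets for dynamic media, scalar-versus-vector
  illumination, a four-level tissue-thickness ladder, and dual-phase
  restoration.

## A worked example

Simulate a tissue-like medium, train the compact desk-scale model, and
evaluate:

```r
library(polspeckle)

config <- dataset_config(grid = 32)       # kappa 0.25, beta 0.3, eta 0.9
ds     <- generate_dataset(config, 500, seed = 1)
model  <- build_model(model_config(input_size = 32), seed = 2)
model  <- train(model, ds, train_config(epochs = 12, seed = 3))

tidy(model)          # per-epoch training log
#> # A tibble: 12 x 3
#>    epoch train_loss test_pcc
#>    <int>      <dbl>    <dbl>
#>  1     1     0.0686    0.356
#>  2     2     0.0591    0.529
#>  ...
#> 11    11     0.0397    0.671
#> 12    12     0.0375    0.684

report <- evaluate(model, ds, model$split$test)
glance(report)
#> # A tibble: 1 x 4
#>     pcc  ssim  psnr n_images
#>   <dbl> <dbl> <dbl>    <int>
#> 1 0.677 0.191  14.3      100
```

A test-split mean PCC of 0.68 from only 400 training pairs means the
restored glyphs already correlate strongly with the ground truth even
though the network only ever saw speckle (the desk-scale benchmark in
the test suite reaches PCC 0.83 with 1,500 training pairs).  SSIM is
deliberately reported unvarnished: windowed structural similarity is
harsh on small sparse-stroke targets, so values around 0.2-0.5 are
typical at this scale even when the strokes are clearly legible.
`autoplot(model)` draws the training curve, `autoplot(report)` the
per-image metric distributions, and `plot_montage(model, ds,
model$split$test[1:4])` shows speckle / truth / restoration triplets.

Physics building blocks are exported individually — e.g. a hologram
round-trip:

```r
tg   <- phase_target(generate_glyph("digit-like", 128, seed = 1))
holo <- encode_hologram(tg, f0 = 16)
rec  <- demodulate_hologram(holo)
phase_rms_error(rec$delta1, tg$delta1)
#> [1] 0.05824761   # binary strokes are not bandlimited; smooth targets
#>                  # demodulate below 0.05 rad
```

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/polspeckle demo --size 64 --seed 1
Rscript inst/cli/polspeckle simulate --config cfg.yaml --out data.rds
Rscript inst/cli/polspeckle experiment --preset thickness --scale desk
```

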