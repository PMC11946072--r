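---
title: "Vectorial speckle restoration: models, simulator design and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vectorial speckle restoration: models, simulator design and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Coherent light traversing biological tissue is scrambled into a speckle
pattern: multiple scattering randomizes phase and intensity, and because
soft tissue is *anisotropic* (muscle fiber, collagen and fat scatter
polarization-dependently), the two orthogonal polarization components of a
vector beam are additionally coupled into one another. Tissue is also
*dynamic* — water evaporation and gravity slowly deform it, so the
scrambling drifts over tens of minutes. `polspeckle` provides a complete,
tested simulation-and-learning pipeline for this setting: it synthesizes
polarization-encoded speckle data from first-principles linear optics and
restores the phase image(s) carried by the two polarization components
with a hybrid convolutional/self-attention network.

## Light propagation model

A monochromatic vector field on an $H\times W$ grid is a pair of complex
amplitude maps $(E_x, E_y)$ (a Jones field). A scattering medium acts as a
2×2-block linear operator on the flattened modes:

$$
\begin{pmatrix}E_{out,x}\\E_{out,y}\end{pmatrix}
=\begin{pmatrix}T_{11}&T_{12}\\T_{21}&T_{22}\end{pmatrix}
\begin{pmatrix}E_{in,x}\\E_{in,y}\end{pmatrix},
$$

the vector transmission matrix (VTM). Isotropic diffusers (ground glass)
have $T_{12}=T_{21}=0$; anisotropic tissue couples the components. The
package realizes this operator in two interchangeable ways:

* **Dense mode** (`sample_dense_vtm()`): the blocks are drawn explicitly.
  Diffuse entries are i.i.d. circular complex Gaussians with variances
  chosen so that the expected transmitted power is $\eta$ times the input
  power, split $(1-\kappa):\kappa$ between co- and cross-polarized
  blocks; a coherent ballistic term $\sqrt{\eta\beta}\,I$ models
  unscattered light. Exact, but $O(N^2)$ in memory, so it is capped at
  small grids — the workhorse for tests, oracles and 32×32 desk
  experiments.
* **Layered mode** (`sample_layered_medium()`): a stack of thin phase
  screens, each a per-pixel unitary Jones matrix (isotropic random phase
  plus a birefringent retarder whose retardance scales with $\kappa$),
  separated by angular-spectrum free-space diffraction. Linear in the
  field and scalable to 256×256.

`effective_vtm()` ties the two together: it materializes the exact dense
operator of a layered medium by propagating all $2N$ canonical basis
fields, and the test suite verifies that dense propagation through this
reconstruction matches layered propagation to better than $10^{-8}$.

### The anisotropy default

$\kappa$ interpolates between ground glass ($\kappa=0$) and complete
polarization mixing ($\kappa=1$... equal split at $0.5$). The package
default is $\kappa = 0.25$: millimetre-scale soft tissue depolarizes only
partially — transmitted light retains a substantial degree of
polarization — and, more importantly, $\kappa=0.5$ is a *degenerate*
study condition for illumination comparisons. At $\kappa=0.5$ and
$\beta=0$, a matched single-phase target produces *identically
distributed* camera images under scalar and vector illumination: each
output component is a circular Gaussian field whose variance sums the co-
and cross-polarized contributions to the same total either way, so total
intensity is the same two-equal-field sum. A comparison run at that point
can only measure noise. At $\kappa=0.25$ the two illuminations are
genuinely different (scalar output intensity has contrast
$\sqrt{(1-\kappa)^2+\kappa^2}\approx0.79$ against the vector field's
$1/\sqrt2$), so polarization-diversity questions have content.

### Numerical choices in the layered medium

* **Smooth screens.** Screen random fields are Gaussian random fields
  with a ~3 px correlation length rather than per-pixel white noise.
  White screens scatter energy beyond the propagating band, where the
  angular-spectrum method must clip it; smooth screens model the strongly
  forward-peaked scattering of soft tissue ($g\sim0.9$) and keep
  propagation unitary — hence the ≤1% power-loss guarantee for
  bandlimited inputs.
* **Wavelength 1.4 px.** With pixels at ~0.7λ the entire sampled spatial
  spectrum lies inside the propagation cone (a high-NA collection
  geometry); evanescent clipping remains implemented for longer
  wavelengths.
* **Drift.** Temporal decorrelation is an autoregressive mixture: each
  generating field $g \leftarrow \sqrt{1-\varepsilon}\,g +
  \sqrt{\varepsilon}\,g_{fresh}$ (an Ornstein–Uhlenbeck step), applied to
  the dense Gaussian blocks or the screen fields. $\varepsilon=0$ is
  frozen, $\varepsilon=1$ a fresh medium; repeated application compounds
  decorrelation monotonically (verified by a Spearman-trend test over 50
  realizations).

### Thickness emulation

Tissue thickness (the 0.5–2.0 mm series) is represented *qualitatively*
via `thickness_ladder()`; published absorption/scattering coefficients
are not used numerically. The knobs that realize "thicker" are lower
transmissivity $\eta$ (0.9 → 0.35), faster *continuous* acquisition-time
decorrelation (per-sample drift rate 0 / 0.015 / 0.035 / 0.09 — a thick
sample's speckle drifts much faster than a thin one's because multiple
scattering amplifies the tissue's micro-motion), and, in layered mode,
more screens (2 → 8). The ballistic fraction is *held fixed* at 0.25
across the ladder.

These choices came out of explicit calibration, and the reasoning is
worth recording. With per-image normalization a noiseless detector
cancels $\eta$ entirely, and per-pixel camera noise is averaged away by
the network across $10^3$ pixels, so neither grades the ladder on its
own. Lowering $\beta$ with thickness — the obvious first choice — turns
out to be *non-monotone*: a stronger coherent background also wastes ADC
range after max-normalization, so reducing $\beta$ can mildly help
reconstruction; hence $\beta$ is not a degradation knob here. What
degrades reconstruction reliably is decorrelation of the medium *during*
acquisition, which makes the speckle-to-image mapping inconsistent
across the training set — no amount of pixel averaging can undo that,
and it is the physical effect the source protocol emphasizes. It is
implemented as an input-side random phase screen (stationary amplitude
2 rad) advancing by an Ornstein–Uhlenbeck step per sample — the
continuous optical-path-length drift of drying tissue — which keeps
dense-medium generation cheap. One further subtlety: *mild* drift acts
as data augmentation and slightly improves test metrics, so the first
nonzero ladder rate is set where the damage clearly exceeds that
benefit.

## Phase encoding

Targets are procedurally generated glyphs (`generate_glyph()`): random
smooth Bezier strokes emulating handwritten digits, plus blob and ring
styles; user images can enter through `read_gray_image()`. A glyph
$g\in[0,1]$ maps to phase $\delta = \pi g$: binary strokes then get
maximal interferometric contrast without hitting the $2\pi\equiv0$ wrap
that would erase them.

The two phase maps ride on orthogonal spatial carriers of a transmittance
hologram,

$$
t(x,y) = 1 + \tfrac{\gamma}{2}\cos(2\pi f_0 x + \delta_1(x,y))
           + \tfrac{\gamma}{2}\cos(2\pi f_0 y + \delta_2(x,y)),
$$

with $f_0$ in cycles per grid width and modulation depth $\gamma\in(0,1]$
(default 1). `demodulate_hologram()` is the idealized 4f
spatial-filtering path: the known unit bias is subtracted, the pattern is
shifted by $f_0$ along each axis, and a Gaussian-edged low-pass disc of
radius $f_0/2$ (edge width $f_0/4$, hard-zeroed beyond $f_0$ so
neighbouring diffraction orders are excluded exactly) isolates the +1
order; the argument of the analytic signal recovers each phase up to a
global constant. Encoding refuses carriers below 4 cycles or too close to
Nyquist for the orders to separate; demodulating a zero-modulation
hologram is an error, not a silent zero. For targets bandlimited below
$f_0/2$ the round-trip RMS phase error is below 0.05 rad; binary strokes
are not bandlimited and demodulate with ringing — the learning pipeline
therefore trains against the glyphs themselves.

The input field (`synthesize_input_field()`) carries $e^{i\delta_1}$ and
$e^{i\delta_2}$ on either the horizontal/vertical or the circular basis
(converted to the x/y Jones frame); scalar mode puts all power in $E_x$
carrying $\delta_1$ only. Total power is $H\cdot W$ in every mode, so
illumination comparisons are at matched power.

## The camera

`record_speckle()` integrates $|E_x|^2+|E_y|^2$ — no analyzer — with
optional Poisson shot noise at a configurable photon budget, additive
Gaussian read noise (in photoelectrons; the mechanism through which low
transmissivity degrades real frames, since read noise does not scale with
the signal), and uniform ADC quantization; each image is then normalized
to $[0,1]$ by its maximum, the standard choice for uncalibrated frames
entering a learning pipeline. The default camera is ideal (noiseless);
the experiment presets use a realistic desk camera of 150 photons per
unit intensity, 3 e⁻ read noise and an 8-bit ADC.

## The restoration network

The network (`build_model()`) has two parallel encoders:

* a four-stage convolutional path (two 3×3 convolutions + ReLU and a 2×2
  max-pool per stage, channels doubling from `cnn_base_channels`), giving
  local texture features and skip connections;
* a self-attention path: the input is cut into $P\times P$ patches, each
  projected to a $K$-dimensional token with a learned positional
  embedding added ($X_{embed}=X W_{proj} + pos_{emb}$), then processed by
  pre-norm multi-head self-attention and GELU feed-forward blocks. The
  final tokens are reshaped onto their patch grid and aligned to the
  bottleneck resolution by average pooling.

Fusion happens at the bottleneck as
`concat(f_cnn, f_attn, f_cnn ⊙ f_attn)` followed by a 1×1 convolution —
the multiplicative term is the interpretation of "multiplication and
concatenation" adopted here; the decoder then upsamples with skip
connections from the convolutional path only, and a sigmoid head emits
one channel (single-phase, SPIR) or two independent channels (dual-phase,
DPIR), so the output always retains the input's spatial size. The
`cnn_baseline` variant is the identical U-shaped path with the attention
path and fusion removed, so measured differences isolate the attention
contribution under a fair-comparison contract (same data, same training
configuration, and — because the convolutional parameters are drawn first
from the same seed — the same convolutional initialization).

Forward and backward passes are written in this package (R orchestration
over BLAS-backed C++ kernels for convolution, pooling and attention);
correctness is anchored by finite-difference gradient checks in the test
suite. Three optimization details are deliberate:

* the sigmoid head bias starts at −1.5 so the initial output sits near
  the sparse-glyph gray level instead of 0.5, and Adam uses a 50-step
  linear warmup — without these, the large uniform error signal of the
  first updates pushed entire ReLU stages permanently dead on most seeds
  at desk scale;
* evaluation uses Polyak-averaged weights (exponential moving average,
  decay 0.97), which damps the step-to-step optimization noise of short
  runs; the raw final-step weights are kept alongside.

### Defaults the source protocol leaves open

Patch size, embedding width, depth, heads, channel counts, loss,
optimizer and schedule are not dictated by the underlying experimental
protocol. Package defaults are $P=16$, $K=256$, 4 attention layers, 8
heads, 32 base channels at 256×256, and a compact $P=8$, $K=32$, 1
attention layer, 2 heads, 4 base channels (≈63k parameters)
configuration at the 32×32 desk scale — the smallest configuration that
clears the desk-scale benchmark (test PCC ≥ 0.75 on a 1,500/300 split)
in about a minute on one CPU. Training uses pixelwise L2 loss on the
normalized glyph labels (L1 available), Adam at $10^{-3}$, batch 16.
Labels are the glyphs rather than the phase maps; with a constant
`phase_scale` the two differ only by a scale factor.

## Datasets and experiments

`generate_dataset()` runs glyph → field → medium → camera end to end and
stores speckle/label pairs with per-sample provenance in a single-file
named-array container. Samples divide into contiguous *acquisition
blocks* sharing a frozen medium state, with `drift_medium()` applied
between blocks — emulating sessions spread over a drying tissue. Every
random draw derives a child seed from the root seed by a fixed counter
scheme, so any sample is reproducible in isolation and containers are
byte-identical across runs. `split_dataset()` implements the 8:2
train/test protocol, stratified across blocks.

`run_experiment()` packages four study designs: `dynamic` (joint
training across four drift sessions T0–T3, per-session evaluation — one
model is trained jointly, matching the generalization claim; per-session
training is the documented alternative), `scalar_vs_vector` (2
illuminations × 2 architectures on the 1.0 mm acquisition-over-time
condition), `thickness` (the four-level ladder) and `dual_phase`
(two-channel restoration; its DPIR model doubles the base width, since
two output channels share the representation). Within a preset all arms
share the same glyphs, medium realization, initialization and batch
order (a paired design), so arm differences are not confounded with
sampling noise; trend conclusions average ≥3 preset seeds. Desk scale is
32×32 with 1,500-sample datasets by default; `n_samples` and `epochs`
trade precision for runtime. The validation suite runs 300–1,800 samples
per dataset and 10–14 epochs so that the full battery — including the
1,500/300-split benchmark and three-seed trend comparisons — completes
in tens of CPU-minutes.

## What the synthetic studies do and do not show

The generator reproduces: fully developed speckle statistics (unit
single-polarization contrast from diffuse dense media), polarization
coupling with a tunable anisotropy, ballistic leakage through thin
media, monotone speckle decorrelation over sessions, photon/read noise
and quantization. Passing tests demonstrate internal consistency of the
optics and the learning pipeline's ability to invert this class of
simulated media — not performance on laboratory tissue data, whose
published metric values depend on an unavailable dataset and are
deliberately not asserted.

One comparison deserves a candid note. For *single-phase* targets this
simulator shows no reliable advantage of vector over scalar illumination:
at $\kappa=0.5$ the two are provably equivalent (see above), and at
$\kappa=0.25$ the measured difference across eight paired seeds is
$-0.002\pm0.004$ PCC — a statistical tie, with the residual asymmetries
(ballistic split, speckle contrast, quantization) pulling in both
directions. The corresponding laboratory observation evidently rests on
mechanisms outside this model class (polarization-dependent detection
efficiency, alignment, structured rather than statistical birefringence).
Where the vector field's advantage is structural — carrying *two distinct
phase images*, which a scalar field cannot do at all — the simulator
reproduces it, and the dual-phase study covers it. The corresponding
trend assertion for single-phase illumination is retained in the
validation suite as specified and may fail; the failure is the
measurement.

## Degenerate inputs and edge cases

Constant images have undefined Pearson correlation (reported as 0 with a
warning); identical images report the PSNR cap (100 dB) instead of
infinity; images smaller than the 11×11 SSIM window fall back to global
statistics with a warning; zero-modulation holograms refuse to
demodulate; dual targets on a scalar field are permitted but flagged,
since the field physically carries only $\delta_1$. Max-pooling breaks
ties toward the first element in column order; training is
bit-reproducible given the configuration seed (single-threaded kernels,
fixed batch order).

## Known limitations

The dense representation is memory-quadratic and capped (48×48 by
default); the layered mode covers larger grids but its anisotropy
parameterization (retardance scale $\kappa\pi$) is an order-of-magnitude
choice, not a calibrated tissue property. Trend margins at the reduced
validation scale are small (hundredths of PCC, tenths of dB); they are
stated as mean comparisons over fixed seeds and are deterministic, but
nearby configurations can flip the thin-end thickness ordering. CPU
training at 256×256 full scale is supported by the same code paths but
slow; the package's validated regime is the desk scale.
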