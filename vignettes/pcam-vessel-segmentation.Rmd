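---
title: "Pyramid channel attention for retinal vessel segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pyramid channel attention for retinal vessel segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcamseg)
```

## The problem

Retinal fundus photographs show the vascular tree as dark curvilinear
structures on a bright circular field of view (FoV). Segmenting vessels
pixel-by-pixel supports early screening for diabetic and hypertensive
retinopathy, but two properties make it hard: vessels occupy a small
fraction of the image (heavy class imbalance), and the clinically
interesting distal vessels are one or two pixels wide, easily lost by an
encoder–decoder that discards spatial detail. `pcamseg` implements a
U-shaped segmentation network with two additions aimed at those failure
modes: a *pyramid channel attention module* (PCAM) that re-weights
multi-scale channel descriptors, and a *pre-activated residual DropBlock
convolution block* (PRDC) that regularises against overfitting on the small
datasets typical of this field.

## The model

### Pyramid channel attention (PCAM)

For an input feature map $F \in \mathbb{R}^{N \times C \times H \times W}$,
spatial pyramid pooling (SPP) applies non-overlapping max pooling with
window sizes 2, 3, 5 and 6 (kernel = stride, ceil mode at borders), then
bilinearly upsamples each pooled map back to $H \times W$ under the
half-pixel convention. The four branches are concatenated channel-wise in
pool-size order into the description set $S$ with $4C$ channels.

Channel attention gates $S$ per channel:

$$M_c(S) = \sigma\!\big(W_1 f(W_0\,\mathrm{avgpool}(S)) +
                        W_1 f(W_0\,\mathrm{maxpool}(S))\big),$$

where the pooling is global over space, $W_0 \in \mathbb{R}^{C'/r \times
C'}$ and $W_1 \in \mathbb{R}^{C' \times C'/r}$ are shared between the two
paths ($C' = 4C$), $f$ is a ReLU and $\sigma$ the sigmoid, so every gate
lies strictly in $(0,1)$. The module output concatenates the input with the
gated description, $[F,\; S \odot M_c(S)]$, and a pre-activated
$1{\times}1$ convolution maps the $5C$ channels back to $C$ so the module
is drop-in inside an encoder stage.

Several points are deliberate design choices where the construction is
genuinely open, and each is switchable:

* **Pooling semantics.** "Max pooling with size $k$" is read as kernel =
  stride = $k$ with ceil mode, which keeps every branch parameter-free and
  matches the subsequent upsampling step. (An alternative reading —
  adaptive pooling to a $k \times k$ output — would make branch geometry
  depend on input size.)
* **Branch combination.** The four branches are concatenated rather than
  summed; concatenation preserves all branch information and lets the
  attention MLP weigh scales against each other.
* **MLP nonlinearity.** A ReLU sits between $W_0$ and $W_1$ (the
  convention of the channel-attention literature); `mlp_relu = FALSE`
  disables it.
* **Reduction ratio.** Default $r = 16$ with hidden width
  $\max(C'/r, 1)$, so thin maps never produce a zero-width layer.
* **Fusion.** `fuse_to_input_channels = TRUE` (default) restores $C$
  channels with BN–ReLU–conv $1{\times}1$; turned off, the raw $5C$
  concatenation is returned.
* **Upsampling convention.** Half-pixel (align-corners off), fixed and
  documented; `spatial_pyramid_pool()` is tested against an independent
  double-loop interpolation oracle.

### Pre-activated residual DropBlock block (PRDC)

The baseline U-Net block is $y = F(x)$ with two conv–BN–ReLU stages
(`plain_conv_block()`). The PRDC block (`prdc_forward()`) is the residual
form $y = x + F(x)$ with the pre-activation ordering
$[\mathrm{BN} \to \mathrm{ReLU} \to \mathrm{conv} \to \mathrm{DropBlock}]
\times 2$ in the branch and an identity shortcut ($1{\times}1$ projection
when channel counts differ).

DropBlock zeroes contiguous $\beta \times \beta$ squares instead of
isolated units. Seeds are planted only in the
$(\omega - \beta + 1) \times (h - \beta + 1)$ interior, at the rate

$$\rho = \frac{(1 - \mathrm{keep\_prob})\,\omega h}
  {\beta^2 (\omega - \beta + 1)(h - \beta + 1)},$$

so the expected dropped fraction is $1 - \mathrm{keep\_prob}$; with
$\beta = 1$ the scheme reduces exactly to Bernoulli dropout. Defaults are
`keep_prob = 0.9`, `block_size = 7` (the defaults of the structured-dropout
literature; the source work does not state its values). Further choices:
kept activations are rescaled by (total/kept) per draw so expected
magnitudes match inference; one mask per sample is shared across channels
(per-channel masks via `shared_channels = FALSE`); `keep_prob` is held
fixed rather than scheduled; DropBlock follows each convolution in the
branch (twice per block). A 10,000-draw Monte-Carlo check in the test suite
confirms the realised drop fraction sits in $0.10 \pm 0.01$ at
$\beta = 5$ on $32 \times 32$ maps — slightly below the nominal 0.1, as
expected from block overlap.

### Network assembly

`build_model()` realises the U-shape: `depth` encoder stages (block →
PCAM → $2{\times}2$ max-pool), a bottleneck block, and mirrored decoder
stages (bilinear $\times 2$ upsample → $1{\times}1$ conv → skip
concatenation → block), ending in a $1{\times}1$ conv and sigmoid. Default
depth 4 and base width 32 (doubling per stage) follow standard U-Net
proportions; the source figure does not state exact widths, so both are
configurable. PCAM output feeds *both* the skip connection and the
downsample path (the placement text — "into the encoder" — leaves this
open; feeding both maximises multi-scale capture). `bottleneck_only`
placement is offered as the minimal alternative. Downsampling is max-pool
and upsampling bilinear-plus-$1{\times}1$-conv, consistent with the
bilinear usage inside SPP. The training loss is unstated in the source;
the default is pixelwise binary cross-entropy with an optional soft-Dice
term (`loss = "bce+dice"`), and evaluation binarises at 0.5.

All forward and backward passes are written explicitly in this package
(with small C++ kernels for patch extraction and pooling); a
finite-difference gradient check on a tiny configuration is part of the
test suite, with DropBlock off so the mapping is deterministic.

## Data pipeline

* **FoV estimation** (`generate_fov_mask()`): red-channel threshold at 0.1
  of the channel maximum, morphological closing, hole filling, largest
  connected component. The red channel has the strongest
  fundus-vs-background contrast; threshold and brush are configurable.
  Evaluation restricts all confusion counts to the FoV (the emphasis the
  protocol places on masks suggests in-FoV evaluation; the alternative is a
  `fov = NULL` pass-through).
* **Resizing** (`resize_sample()`): bilinear for images,
  nearest-neighbour + re-binarisation for masks, so labels never become
  fractional.
* **Augmentation** (`augment_sample()`): one shared geometric transform
  (rotation ±15°, flip p = 0.5, shift ±10 %, zoom 0.9–1.1) applied by
  inverse affine resampling — bilinear for the image, nearest for masks —
  plus photometric jitter (±0.2 brightness/contrast/saturation) on the
  image only. The ranges are repository conventions; the protocol lists
  the transform families without parameters.
* **Patch inference** (`make_patch_grid()`, `stitch_patches()`): default
  128/64 with overlap averaging; the final origin per axis is clamped so
  coverage is complete. Coordinates are 0-based, row-major, half-open.
* **Splits** (`make_folds()`): presets for the fixed 20/20 and 20/8
  protocols and the 10-fold 18/2 rotation for the 20-image dataset.

## The phantom generator

`generate_phantom()` emulates the features of fundus data the pipeline
depends on: a bright circular FoV on a dark surround, branching curvilinear
foreground grown as random-walk trees from FoV-boundary entry points,
stroke width tapering toward the tips (children inherit 70 % of the parent
width), anti-aliased rendering for the image with a hard-thresholded mask,
a linear background intensity gradient, and Gaussian noise. Vessels are
darker than background, as in the green/red channels of real images. The
vessel fraction of the FoV is constrained to 5–15 % (resampling with an
adapted tree count, failing explicitly after 25 attempts), mirroring the
foreground/background imbalance of real data.

What the phantoms do **not** emulate: lesions and exudates, the optic disc,
texture and JPEG artefacts, physiologically realistic branching
(Murray-law radii, fractal statistics), or vessel central reflex. Passing
the phantom-based checks therefore demonstrates that the architecture,
gradients, data handling and metrics are correct and that the model can
learn curvilinear structure at desk scale — not that any particular
clinical benchmark score is reproduced. The published benchmark rows enter
the package only as inputs to the metric-identity and delta arithmetic.

## Numerical choices and degenerate inputs

* Batch norm: $\varepsilon = 10^{-5}$, running-statistic momentum 0.1;
  inference uses running statistics.
* Initialisation: He-normal for convolutions and MLPs, deterministic under
  a build seed.
* Max-pool ties resolve to the first index in column-major order;
  binarisation uses `>=` so ties at the threshold become foreground.
* Zero-denominator metrics return 1 when the condition is vacuous (no
  pixels of that class and none predicted) with a logged message; fully
  empty confusion tables are an error.
* Geometry errors are explicit: pool windows larger than the map, patch
  sizes larger than the image, inputs not divisible by $2^{\mathrm{depth}}$
  (with pad-to-multiple advice), channel mismatches.

## Problem sizes used by the checks

The test-suite and acceptance-script runs use desk-scale configurations
chosen as the package's own convention: $64 \times 64$ phantoms; a depth-2,
base-8 model trained 5 epochs on 30 phantoms with 6 held out
(learning-signal check, short-schedule recipe `bce+dice`, Adam,
learning rate $2 \times 10^{-3}$, batch 2); a four-variant ablation grid
(baseline, +PCAM, +PRDC, +PCAM+PRDC) of depth-2, base-8 models sharing one
data stream and seed (10/4 phantoms at one epoch in the determinism test,
30/6 at five epochs in the reproduction script); and 10,000 Monte-Carlo
DropBlock draws. The full-scale defaults (depth 4, base 32, patch 128/64,
50 epochs) remain available for real datasets.

## Known limitations

* The network runs on CPU in R; it is sized for method study, testing and
  small images, not for high-resolution clinical throughput.
* Absolute benchmark scores on DRIVE/CHASE_DB1/STARE require the original
  datasets and long training runs; the package supports that workflow
  (loaders, folds, patch inference, training) but its automated checks do
  not claim those numbers.
* GIF masks (shipped by one public dataset) must be converted to PNG/TIFF
  before loading; no installed reader handles GIF.
* `aggregate_reports()` offers pooled (default) and per-image mean
  aggregation; published tables rarely state which is used, and the two
  differ on imbalanced pairs — the identity $F1 = 2\,\mathrm{IOU} /
  (1 + \mathrm{IOU})$ holds only within one confusion table, which is
  visible in cross-validated table rows.
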