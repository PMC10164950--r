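---
title: "Methods: attention-and-cross U2Net segmentation and organoid growth quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attention-and-cross U2Net segmentation and organoid growth quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Problem and model

Brightfield micrographs of 3D organoid cultures show bright, roughly
elliptical bodies with darker rims on a textured, unevenly illuminated
background. The segmentation task is pixel-level binary classification
(organoid vs background), and the downstream quantity of interest is the
projected area of each organoid, grouped by treatment and culture day.

The network is a nested U-structure. Each of the eleven stages is a
residual U-block (RSU): an input convolution `C_in → C_out`, an L-level
U-shaped encoder-decoder over `M` mid channels, and a residual sum. The
encoder levels are L = 7, 6, 5, 4 followed by two dilated RSU-4D stages
(rates 1, 2, 4, 8; all internal features stay at the stage resolution);
decoders mirror the encoders. Stages are joined by 2×2 max pooling (ceil
mode), giving a 1/32 bottleneck. Deep supervision comes from six 1-channel
side outputs (bottleneck plus each decoder), upsampled to input size.

Two modules modify the plain backbone. The Grouping Cross Merge (GCM)
replaces skip concatenation: shallow and deep maps are split into *n*
channel groups, matching groups are concatenated and halved by a 1×1
convolution, the groups re-concatenated (giving `(C_s + C_d)/2` channels),
and a residual projection of the deep input added; GCM outputs are chained
deep-to-shallow so fused features propagate to the shallowest skip. The
channel law is what makes the published decoder input widths come out
exactly (e.g. the final decoder consumes (64+64)/2 = 64 channels). The
Residual Attention Gate (RAG) sits on the shallowest skip: the fused map
`φ = ReLU(a(x) + b(upsample₂(g)))` is filtered to `d(φ)`, globally pooled,
passed through a two-layer channel bottleneck (`c → max(4, c/r) → c`) and a
sigmoid, and the resulting per-channel weights reweight `d(φ)` with a
residual add. The gated feature goes through dropout and a 1×1 classifier;
its logits are averaged with the 1×1-convolved splice of the six side-output
logits before the final sigmoid.

The objective is `L_BCE + L_Dice` per supervised map, summed over the fused
map and all six side outputs. Soft Dice uses the standard
`1 − (2Σpy + s)/(Σp + Σy + s)` form with smoothing `s = 1`; the BCE clamps
probabilities to `[1e-7, 1 − 1e-7]`.

## Design choices in detail

Several aspects of the architecture admit more than one reading; the
package fixes them as follows.

* **Normalization.** Convolution units are conv + per-sample channelwise
  spatial normalization (instance normalization, learnable gain/bias) +
  ReLU. Instance norm was chosen over batch norm because the engine
  processes samples singly (minibatches are gradient accumulation), making
  per-sample statistics exact, batch-size independent and deterministic.
  The GCM's group convolutions and carry projections are also normalized
  units: the serial GCM chain otherwise compounds unnormalized additions
  (group merge + residual + carry) across five skips, which measurably
  inflates feature scale toward the shallow end and saturates the attention
  gate. The residual path of the GCM stays a pure projection (identity when
  channel counts agree), so zeroing every convolution reduces the module to
  the deep-input residual.
* **GCM group counts.** The shallow/middle/deep bands are n = 4 (two
  shallowest skips), 6 (middle), 8 (two deepest). A group count must divide
  both incoming channel counts; with the standard power-of-two channel
  table the middle skip (256 channels) is not divisible by 6, so the
  constructor substitutes the largest admissible value from {8, 6, 4, 2, 1}
  (here 8) at assembly time. `gcmConfig(strict = TRUE)` turns the
  substitution into a build-time error; custom width tables divisible by 6
  use the requested value.
* **Serial chain direction.** GCMs run deepest-first; each output is
  resized, projected and summed into the next shallower GCM's deep input.
  The shallowest GCM's output both feeds the final decoder and the RAG —
  the only reading in which "the last GCM" can feed the attention gate and
  then the final 1×1 classifier.
* **RAG attachment and fusion.** One RAG, at full resolution, gated by the
  second decoder's output (exactly half resolution, as the gate's shape
  contract requires). How the RAG classifier combines with the splice of
  the six side maps is genuinely open; the default averages the two logit
  maps, and `networkConfig(fusionMode = "splice" | "rag")` exposes both
  single-branch readings.
* **Dropout placement.** p = 0.5, immediately before the final 1×1
  classification convolution — the only classifier layer named.
* **Deep supervision.** The loss is applied per side output and summed with
  the fused map (`deepSupervision = FALSE` restricts to the fused map);
  without it the side heads would receive no gradient.
* **Mid-channel widths.** `M` per stage is not determined by the
  input/output table; the package adopts the canonical full-size values
  (encoders 32, 32, 64, 128, 256, 256; decoders mirrored) and scales all
  widths with `backboneConfig(widthScale=)` for desk-scale models.
* **Initialization.** He-uniform for convolutions and FC layers, zero
  biases, unit gains — drawn from R's RNG so a seed fixes the build;
  upsampling is bilinear with corner alignment disabled throughout.

## Data preparation

* **Denoising** is non-local means (patch 7, search window 21, strength 10
  by default — common settings for 8-bit micrographs), implemented per
  channel with clamped borders.
* **Augmentation** draws, per tile, an independent (hflip, vflip, isotropic
  scale in [0.8, 1.25], crop) and applies identical geometry to image
  (bilinear) and mask (nearest-neighbour, keeping masks binary). 32 tiles
  per source turn 200 sources into 6400 tiles of 256×256. Every tile logs
  its transform so the geometry can be re-applied and checked exactly.
* **Splitting** is 8:1:1 by default with a leakage guard: whole sources are
  assigned to partitions, so augmented copies of one micrograph never span
  train and test. Target sizes are `round(ratio·N)` for validation and
  test with the remainder in train; with equal tiles per source the counts
  are exact.
* **Rasterization** of polygon annotations uses pixel-center,
  boundary-inclusive point-in-polygon testing (0-based coordinates, origin
  top-left, x = column), so the operation has an exact brute-force oracle.

## Training and inference

SGD with momentum 0.9, learning rate 0.01, batch size 8 and no schedule are
the defaults (none of these is determined by the reference setup beyond
"SGD, 1000 epochs, dropout 0.5"); all are exposed in `trainConfig()`. Model
selection keeps the epoch with the best validation F1 — F1 being the
headline metric of this problem — and a non-finite loss aborts with the
epoch and batch index. Full-size micrographs are segmented by sliding
windows (tile 256, overlap 32 by default) with probability averaging in
overlaps and binarization at 0.5 (configurable); images smaller than the
tile are reflect-padded.

Dataset-level metrics pool confusion counts over images (micro-averaging);
macro-averaging is available behind a flag since the choice is not fixed by
the metric definitions.

## Synthetic data: what it emulates and what it does not

The scene generator renders the appearance the model must cope with:
elliptical organoids of heterogeneous size (optionally radially perturbed
boundaries), brighter interiors with darker rims, a low-frequency textured
background, a smooth multiplicative illumination field and additive
Gaussian noise, with the mask exactly the union of rendered footprints.
The drug-screen fixture draws per-organoid areas from a log-normal
distribution whose location parameter is shared by all groups on days 1–3
and raised for untreated controls from day 5 (+0.6 log units at day 5,
+0.9 at day 7; spread 0.35) — growth inhibition by both drugs, emerging
after the initial growth phase.

Synthetic scenes do **not** contain several features of real micrographs:
organoid internal texture and lumen structure, adhesion and partial overlap
of neighbouring organoids, debris, out-of-focus blur, or day-7 background
complexity. Passing tests therefore demonstrate that the architecture,
losses, optimization and quantification pipeline are implemented correctly
and can fit data of this geometry — not that the trained weights transfer
to real cultures, which requires real annotated images at realistic
training scale.

## Numerical choices and degenerate inputs

* BCE clamp 1e-7; Dice smooth 1.0 (training) with the `smooth → 0` limits
  used for analytic checks.
* Undefined metric ratios (e.g. sensitivity with no true foreground) return
  `NaN` with a warning, never a silent 0 or 1.
* Quantiles are linear-interpolation type 7, so summaries are portable
  across implementations.
* Connected components default to 8-connectivity with a 30-px minimum area
  (speckle suppression at 256×256 tile scale); both are parameters, and
  touching organoids deliberately remain one component — separating
  adherent organoids is out of scope for binary segmentation.
* Max pooling uses ceil mode; an RSU whose level would pool a feature below
  1×1 raises an error at forward time naming the offending configuration.
* Checkpoints embed the resolved configuration and a structural hash,
  verified on load.

## Problem sizes used by the tests and acceptance script

Unit tests run width-scaled models (1/16 and 1/8 of the full channel
table) on 64–96 px tiles; the architecture-conformance check runs the
full-width model once at 3×256×256. The trainability check overfits eight
synthetic 96×96 tiles with the 1/8-width model for 15 epochs. The counting
law streams 200 synthetic 336×336 sources through the augmenter one at a
time. These sizes keep every check to minutes on a single CPU while
exercising the full code paths; they are the package's chosen study
conditions, stated here so results are interpreted at the scale they were
computed.

## Known limitations

The engine is CPU-only and single-threaded apart from BLAS; full-width
training at the reference scale (6400 tiles, up to 1000 epochs) is outside
its intended use — it exists to make the architecture and training
procedure exact, testable and reproducible at desk scale. Instance
normalization deviates from the batch normalization of canonical U2Net
implementations. Benchmark scores against real bladder-cancer organoid
datasets are not reproduced here: the reference dataset is not public, and
no claim is made beyond what the package's own tests compute.
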