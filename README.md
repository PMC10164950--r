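# organoidSeg

Pixel-level segmentation of brightfield organoid micrographs and automated
quantification of organoid growth for drug screening.

Organoids — 3D multicellular cultures grown from patient or cell-line
material — are imaged repeatedly over a culture course (e.g. days 1, 3, 5,
7) with and without drug treatment, and the readout of interest is the
projected area of every organoid in every image. Measuring those areas by
hand (ImageJ-style outlining) is the throughput bottleneck of organoid drug
screens. `organoidSeg` implements an attention-augmented nested U-structure
network (ACU2Net) that segments organoids from the background, plus the full
surrounding pipeline: synthetic ground-truth data, annotation handling,
preprocessing, training, evaluation and per-organoid growth statistics.

## The model

The backbone is a U²-Net: a six-encoder / five-decoder encoder-decoder in
which every stage is itself a small U-shaped network, the *residual U-block*
(RSU). An RSU-L maps `C_in → C_out` through an input convolution, an
L-level encoder-decoder over `M` mid channels (2×2 max-pool descents,
bilinear ascents, skip concatenations), and a residual sum of the two paths;
the first encoder stage uses L = 7. The two deepest encoder stages and the
deepest decoder use the dilated variant RSU-4D (dilation rates 1, 2, 4, 8),
which keeps all internal features at the stage resolution. Encoder stages
are joined by 2×2 max pooling, so the bottleneck feature is 1/32 of the
input side. Six side-output heads (3×3 convolution + sigmoid, upsampled to
input size) provide deep supervision from the bottleneck and every decoder
stage.

Two modules augment the plain backbone:

* **GCM (Grouping Cross Merge)** replaces plain skip concatenation. The
  encoder ("shallow") and decoder-side ("deep") feature maps are each split
  channelwise into *n* groups (n = 4 / 6 / 8 from shallow to deep skips);
  matching groups are concatenated and passed through a 1×1 convolution that
  halves each pair, so the merged output has `(C_s + C_d)/2` channels, and a
  residual projection of the deep input is added. Successive GCMs are
  serially linked deep-to-shallow, carrying fused features toward the
  shallowest skip.
* **RAG (Residual Attention Gate)** gates the shallowest skip feature `x`
  with the next-coarser decoder feature `g` (half resolution):
  `φ = ReLU(a(x) + b(upsample₂(g)))`, `d(φ)` a further 1×1 convolution,
  global average pooling and a two-layer bottleneck (`c → c/r → c`, r the
  reduction ratio) with a sigmoid give per-channel weights `A ∈ (0,1)^c`,
  and the output is `o_f = Σ_k A_k·d(φ)_k + d(φ)`. The gated feature passes
  through dropout (p = 0.5) and a 1×1 classifier; its logits are fused with
  the splice of the six side outputs to form the final probability map.

Training minimizes `L = L_BCE + L_Dice` — mean binary cross-entropy plus
soft Dice loss `1 − (2Σpy + s)/(Σp + Σy + s)` — summed over the fused map
and the six side outputs, with SGD (momentum 0.9 by default). Evaluation
uses pixel confusion counts: accuracy `(TP+TN)/N`, sensitivity `TP/(TP+FN)`,
specificity `TN/(TN+FP)` and `F1 = 2TP/(2TP+FP+FN)`.

Because no deep-learning framework is required, the package ships its own
compact CPU engine: reverse-mode autodiff over im2col/GEMM convolution,
max-pooling, bilinear resampling, normalization, attention and the fused
loss gradients (Rcpp/RcppArmadillo kernels).

## Worked example

```r
library(organoidSeg)
setGlobalSeed(42)

# 1. synthetic study data: eight annotated 96x96 tiles
tiles <- lapply(1:8, function(i) {
  sp <- sceneSpec(width = 96, height = 96, nOrganoids = 3,
                  radiusRange = c(8, 18), noiseSigma = 6, seed = 100 + i)
  generateSyntheticScene(sp, source_id = paste0("t", i))
})
tiles[[1]]
#> AnnotatedImage 96x96 (t1)
#>   foreground: 904 px (9.8%)
#>   day 1, group CTR, pixel size 1 um

# 2. a scaled-down network, trained to overfit the tiles
model <- acu2net(networkConfig(backbone = backboneConfig(widthScale = 1/8)),
                 seed = 7)
countParams(model)
#> [1] 645410
fit <- trainModel(model, tiles,
                  cfg = trainConfig(epochs = 10, learningRate = 0.05,
                                    batchSize = 4, seed = 11))
tail(fit$log[, c("epoch", "train_loss", "val_F1")], 3)
#>    epoch train_loss    val_F1
#> 8      8   3.817613 0.8985449
#> 9      9   3.387819 0.9139089
#> 10    10   3.158191 0.9299790

# 3. segmentation metrics on one tile
pred <- predictMask(fit$model, tiles[[1]], tile = 96, overlap = 0)
segMetrics(confusionCounts(pred, maskArray(tiles[[1]])))
#>       Acc        Se        Sp        F1
#> 0.9891493 0.9933628 0.9886910 0.9472574

# 4. screening quantification from the predicted mask
rec <- measureOrganoids(labelComponents(pred, 8, 30), tiles[[1]])
rec[, c("organoid_id", "area_pixels", "centroid_row", "centroid_col")]
#>   organoid_id area_pixels centroid_row centroid_col
#> 1           1         992     69.52722     71.10786
```

The training F1 is the pixel F1 of the thresholded fused map against the
ground-truth masks (here the model overfits eight tiles, as intended for a
smoke test); the per-organoid table is what the screening pipeline
aggregates into per-group, per-day medians and quartiles
(`summarizeGroups()`, `exportViolinData()`).

A command-line front end (`inst/exec/organoidseg`) wraps the same functions:
`generate`, `inspect`, `evaluate`, `segment`, `screen` and `train`
subcommands.

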