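Package: organoidSeg
Title: Attention and Cross U2Net Segmentation and Growth Quantification of
    Organoid Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Semantic segmentation of brightfield organoid micrographs with an
    attention-augmented nested U-structure network (ACU2Net): residual U-blocks
    (RSU), a six-encoder/five-decoder U2Net backbone with deep supervision,
    Grouping Cross Merge (GCM) skip-fusion modules and a Residual Attention
    Gate (RAG), trained with a combined binary cross-entropy and soft Dice
    objective. Includes a self-contained CPU neural-network engine
    (convolution, pooling, bilinear resampling, reverse-mode autodiff, SGD),
    a synthetic organoid-scene generator with pixel-level ground truth,
    Labelme-style polygon annotation rasterization, non-local-means denoising,
    dataset augmentation and leakage-safe splitting, pixel-confusion
    evaluation metrics, sliding-window inference for full-size micrographs,
    and a drug-screening pipeline that measures per-organoid areas and
    summarizes growth by treatment group and culture day.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    pracma,
    png,
    EBImage,
    S4Vectors,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
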