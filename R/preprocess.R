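# ---------------------------------------------------------------------------
# Dataset preparation: non-local-means denoising, augmentation of source
# micrographs into fixed-size training tiles (random flip / scale / crop
# with identical geometry on image and mask), and leakage-safe splitting.
# ---------------------------------------------------------------------------

#' Non-local-means denoising
#'
#' Patch-similarity-weighted averaging: each pixel is replaced by the
#' weighted mean of pixels in its search window, weighted by
#' `exp(-patchSSD / strength^2)` where patchSSD is the mean squared
#' difference between the surrounding patches. Removes acquisition noise
#' while preserving organoid edges; a constant image is returned unchanged
#' (up to quantization).
#'
#' @param image `H x W x 3` array (0..255), `H x W` matrix, or
#'   [AnnotatedImage-class].
#' @param strength filtering strength h in intensity units (default 10).
#' @param patchSize odd patch side (default 7).
#' @param searchWindow odd search-window side (default 21); must be >=
#'   `patchSize`.
#' @return Same type as the input, denoised.
#' @export
denoiseImage <- function(image, strength = 10, patchSize = 7L,
                         searchWindow = 21L) {
  if (patchSize %% 2L == 0L || searchWindow %% 2L == 0L)
    stop("patchSize and searchWindow must be odd")
  if (patchSize > searchWindow)
    stop("patchSize must not exceed searchWindow")
  if (inherits(image, "AnnotatedImage")) {
    out <- image
    out@image <- denoiseImage(imageArray(image), strength, patchSize, searchWindow)
    return(out)
  }
  was_matrix <- is.matrix(image)
  arr <- if (was_matrix) array(as.numeric(image), c(dim(image), 1L))
         else array(as.numeric(image), dim(image))
  den <- cpp_nlm_denoise(arr, strength, patchSize, searchWindow)
  den <- round(pmin(pmax(den, 0), 255))
  if (was_matrix) {
    m <- den[, , 1L]
    storage.mode(m) <- "integer"
    m
  } else {
    storage.mode(den) <- "integer"
    den
  }
}

#' Augmentation configuration
#'
#' Each emitted tile is an independent random draw of (horizontal flip,
#' vertical flip, isotropic scale, crop position) applied identically to
#' the image (bilinear) and its mask (nearest-neighbour, so masks stay
#' binary). 32 tiles per source turn a 200-image dataset into 6400 tiles.
#'
#' @param tileSize output tile side in pixels (>= 32, default 256).
#' @param tilesPerImage tiles drawn per source image (default 32).
#' @param allowHflip,allowVflip enable random flips.
#' @param scaleRange `c(min, max)` isotropic scale factors (default
#'   `c(0.8, 1.25)`).
#' @param seed integer RNG seed.
#' @return Object of class `augmentationConfig`.
#' @export
augmentationConfig <- function(tileSize = 256L, tilesPerImage = 32L,
                               allowHflip = TRUE, allowVflip = TRUE,
                               scaleRange = c(0.8, 1.25), seed = 1L) {
  stopifnot(tileSize >= 32, tilesPerImage >= 1,
            length(scaleRange) == 2L, scaleRange[1L] > 0,
            scaleRange[1L] <= scaleRange[2L])
  structure(list(tileSize = as.integer(tileSize),
                 tilesPerImage = as.integer(tilesPerImage),
                 allowHflip = isTRUE(allowHflip), allowVflip = isTRUE(allowVflip),
                 scaleRange = as.numeric(scaleRange), seed = as.integer(seed)),
            class = "augmentationConfig")
}

# Extract one tile given explicit transform parameters; used by the
# augmenter and exposed so a logged transform can be re-applied.
extractTile <- function(sample, tileSize, scale, r0, c0, hflip, vflip) {
  img <- array(as.numeric(imageArray(sample)), dim(imageArray(sample)))
  timg <- cpp_window_bilinear(img, tileSize, tileSize, scale, r0, c0)
  tmask <- cpp_window_nearest(maskArray(sample), tileSize, tileSize, scale, r0, c0)
  if (hflip) { timg <- timg[, tileSize:1, , drop = FALSE]; tmask <- tmask[, tileSize:1] }
  if (vflip) { timg <- timg[tileSize:1, , , drop = FALSE]; tmask <- tmask[tileSize:1, ] }
  timg <- round(pmin(pmax(timg, 0), 255))
  list(image = timg, mask = matrix(as.integer(tmask), tileSize, tileSize))
}

#' Augment source images into training tiles
#'
#' Emits `length(samples) * tilesPerImage` tiles of `tileSize x tileSize`,
#' each with its transform parameters logged in
#' `metadata(tile)$transform` (scale, crop offsets in scaled coordinates,
#' flips) so the geometry can be re-applied and checked. Metadata is
#' inherited from the source; `source_id` is preserved for leakage-safe
#' splitting.
#'
#' @param samples list of [AnnotatedImage-class] sources; every source must
#'   be at least `tileSize` in both dimensions at the minimum scale.
#' @param cfg an [augmentationConfig()].
#' @return List of `AnnotatedImage` tiles.
#' @export
augmentDataset <- function(samples, cfg) {
  stopifnot(inherits(cfg, "augmentationConfig"), length(samples) >= 1L)
  ts <- cfg$tileSize; smin <- cfg$scaleRange[1L]
  for (s in samples) {
    d <- dim(imageArray(s))
    if (floor(d[1L] * smin) < ts || floor(d[2L] * smin) < ts)
      stop("source '", metadata(s)$source_id, "' (", d[1L], "x", d[2L],
           ") is smaller than the ", ts, "-px tile at minimum scale ",
           smin, "; enlarge the source or reduce tileSize/scaleRange")
  }
  set.seed(cfg$seed)
  out <- vector("list", length(samples) * cfg$tilesPerImage)
  k <- 0L
  for (s in samples) {
    d <- dim(imageArray(s))
    for (t in seq_len(cfg$tilesPerImage)) {
      sc <- stats::runif(1, cfg$scaleRange[1L], cfg$scaleRange[2L])
      hs <- floor(d[1L] * sc); ws <- floor(d[2L] * sc)
      r0 <- sample.int(hs - ts + 1L, 1L) - 1L
      c0 <- sample.int(ws - ts + 1L, 1L) - 1L
      hf <- cfg$allowHflip && stats::runif(1) < 0.5
      vf <- cfg$allowVflip && stats::runif(1) < 0.5
      tl <- extractTile(s, ts, sc, r0, c0, hf, vf)
      meta <- metadata(s)
      meta$transform <- list(scale = sc, r0 = r0, c0 = c0,
                             hflip = hf, vflip = vf)
      meta$tile_index <- t
      k <- k + 1L
      out[[k]] <- AnnotatedImage(tl$image, tl$mask,
                                 source_id = meta$source_id,
                                 culture_day = meta$culture_day,
                                 group_label = meta$group_label,
                                 pixel_size_um = meta$pixel_size_um,
                                 meta = meta)
    }
  }
  out
}

#' Split specification
#'
#' @param ratios train/validation/test proportions, nonnegative, summing to
#'   1 (default 0.8/0.1/0.1).
#' @param seed integer RNG seed for the shuffle.
#' @return Object of class `splitSpec`.
#' @export
splitSpec <- function(ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(ratios) == 3L, all(ratios >= 0))
  if (abs(sum(ratios) - 1) > 1e-9) stop("split ratios must sum to 1")
  structure(list(ratios = as.numeric(ratios), seed = as.integer(seed)),
            class = "splitSpec")
}

#' Leakage-safe dataset split
#'
#' Partitions samples into train/validation/test. Target sizes are
#' `round(ratio * N)` for validation and test with the remainder in train,
#' and all tiles sharing a `source_id` land in the same partition, so
#' augmented copies of one micrograph can never leak across splits.
#'
#' @param samples list of [AnnotatedImage-class] tiles, or a data.frame
#'   with a `source_id` column (rows are then split).
#' @param spec a [splitSpec()].
#' @return Named list `train`, `val`, `test` of the same type as the input.
#' @export
splitDataset <- function(samples, spec = splitSpec()) {
  stopifnot(inherits(spec, "splitSpec"))
  is_df <- is.data.frame(samples)
  n <- if (is_df) nrow(samples) else length(samples)
  if (n < 3L) stop("need at least 3 samples to split")
  src <- if (is_df) samples$source_id
         else vapply(samples, function(s) metadata(s)$source_id, character(1))
  set.seed(spec$seed)
  sources <- sample(unique(src))
  sizes <- vapply(sources, function(g) sum(src == g), numeric(1))
  t_test <- round(spec$ratios[3L] * n)
  t_val <- round(spec$ratios[2L] * n)
  assign_to <- setNames(rep("train", length(sources)), sources)
  n_test <- 0; n_val <- 0
  for (i in seq_along(sources)) {
    if (n_test + sizes[i] <= t_test) {
      assign_to[sources[i]] <- "test"; n_test <- n_test + sizes[i]
    } else if (n_val + sizes[i] <= t_val) {
      assign_to[sources[i]] <- "val"; n_val <- n_val + sizes[i]
    }
  }
  part <- assign_to[src]
  pick <- function(lbl) if (is_df) samples[part == lbl, , drop = FALSE]
                        else samples[part == lbl]
  list(train = pick("train"), val = pick("val"), test = pick("test"))
}
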