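test_that("denoising leaves a constant image unchanged", {
  img <- array(128L, c(20, 20, 3))
  out <- denoiseImage(img, strength = 10, patchSize = 5, searchWindow = 9)
  expect_identical(out, { storage.mode(img) <- "integer"; img })
})

test_that("denoising reduces deviation from the clean image", {
  sp <- sceneSpec(width = 48, height = 48, nOrganoids = 2,
                  radiusRange = c(8, 12), noiseSigma = 0, seed = 21)
  clean <- imageArray(generateSyntheticScene(sp))
  set.seed(22)
  noisy <- clean + array(rnorm(length(clean), 0, 20), dim(clean))
  noisy <- round(pmin(pmax(noisy, 0), 255))
  den <- denoiseImage(noisy, strength = 20, patchSize = 5, searchWindow = 11)
  madBefore <- mean(abs(noisy - clean))
  madAfter <- mean(abs(den - clean))
  expect_lt(madAfter, madBefore)
})

test_that("denoising at zero strength is a no-op and windows must be odd", {
  set.seed(3)
  img <- round(array(runif(12 * 12 * 3, 0, 255), c(12, 12, 3)))
  out <- denoiseImage(img, strength = 0, patchSize = 3, searchWindow = 7)
  expect_lte(max(abs(out - img)), 1)
  expect_error(denoiseImage(img, patchSize = 4), "odd")
  expect_error(denoiseImage(img, patchSize = 9, searchWindow = 7), "exceed")
})

test_that("augmentation count law holds for any input count", {
  for (nsrc in c(1L, 3L)) {
    src <- makeTiles(nsrc, size = 96, seedBase = 40L)
    cfg <- augmentationConfig(tileSize = 64, tilesPerImage = 5, seed = 2)
    tiles <- augmentDataset(src, cfg)
    expect_length(tiles, nsrc * 5L)
    expect_true(all(vapply(tiles, function(t)
      identical(dim(imageArray(t)), c(64L, 64L, 3L)), logical(1))))
    expect_true(all(vapply(tiles, function(t)
      all(maskArray(t) %in% c(0L, 1L)), logical(1))))
  }
})

test_that("identity augmentation returns the source tile unchanged", {
  src <- makeTiles(1, size = 64, seedBase = 50L)
  cfg <- augmentationConfig(tileSize = 64, tilesPerImage = 1,
                            allowHflip = FALSE, allowVflip = FALSE,
                            scaleRange = c(1, 1), seed = 1)
  tiles <- augmentDataset(src, cfg)
  expect_identical(imageArray(tiles[[1L]]), imageArray(src[[1L]]))
  expect_identical(maskArray(tiles[[1L]]), maskArray(src[[1L]]))
  expect_identical(metadata(tiles[[1L]])$source_id, "tile1")
})

test_that("re-applying the logged transform reproduces every tile mask", {
  src <- makeTiles(2, size = 96, seedBase = 60L)
  cfg <- augmentationConfig(tileSize = 64, tilesPerImage = 4, seed = 9)
  tiles <- augmentDataset(src, cfg)
  bySrc <- setNames(src, vapply(src, function(s) metadata(s)$source_id,
                                character(1)))
  for (t in tiles) {
    tr <- metadata(t)$transform
    s <- bySrc[[metadata(t)$source_id]]
    # independent nearest-neighbour re-application of the logged geometry
    sm <- maskArray(s)
    H <- nrow(sm); W <- ncol(sm)
    re <- matrix(0L, 64, 64)
    for (j in 0:63) for (i in 0:63) {
      sr <- min(max(floor((tr$r0 + i + 0.5) / tr$scale), 0), H - 1)
      sc <- min(max(floor((tr$c0 + j + 0.5) / tr$scale), 0), W - 1)
      re[i + 1L, j + 1L] <- sm[sr + 1L, sc + 1L]
    }
    if (tr$hflip) re <- re[, 64:1]
    if (tr$vflip) re <- re[64:1, ]
    expect_identical(maskArray(t), re)
  }
})

test_that("augmentation is deterministic for a fixed seed", {
  src <- makeTiles(1, size = 96, seedBase = 70L)
  cfg <- augmentationConfig(tileSize = 64, tilesPerImage = 3, seed = 5)
  a <- augmentDataset(src, cfg)
  b <- augmentDataset(src, cfg)
  for (i in seq_along(a))
    expect_identical(imageArray(a[[i]]), imageArray(b[[i]]))
})

test_that("sources smaller than the tile at minimum scale are rejected", {
  src <- makeTiles(1, size = 64, seedBase = 80L)
  cfg <- augmentationConfig(tileSize = 64, tilesPerImage = 1,
                            scaleRange = c(0.8, 1.25))
  expect_error(augmentDataset(src, cfg), "smaller than")
})

test_that("split sizes follow round(ratio*N) with remainder to train", {
  df <- data.frame(source_id = sprintf("s%03d", 1:200))
  df <- df[rep(1:200, each = 32), , drop = FALSE]   # 6400 tiles
  parts <- splitDataset(df, splitSpec(c(0.8, 0.1, 0.1), seed = 3))
  expect_identical(nrow(parts$train), 5120L)
  expect_identical(nrow(parts$val), 640L)
  expect_identical(nrow(parts$test), 640L)
  # leakage guard: no source in two partitions
  expect_length(intersect(parts$train$source_id, parts$test$source_id), 0L)
  expect_length(intersect(parts$train$source_id, parts$val$source_id), 0L)
  expect_length(intersect(parts$val$source_id, parts$test$source_id), 0L)
})

test_that("split partitions are exhaustive and disjoint on samples", {
  tiles <- augmentDataset(makeTiles(3, size = 96, seedBase = 90L),
                          augmentationConfig(tileSize = 64, tilesPerImage = 4,
                                             seed = 8))
  parts <- splitDataset(tiles, splitSpec(c(0.5, 0.25, 0.25), seed = 1))
  expect_identical(length(parts$train) + length(parts$val) + length(parts$test),
                   length(tiles))
  ids <- function(x) vapply(x, function(s) metadata(s)$source_id, character(1))
  expect_length(intersect(ids(parts$train), ids(parts$test)), 0L)
})

test_that("degenerate and invalid split specs behave per contract", {
  df <- data.frame(source_id = sprintf("s%d", 1:10))
  all_train <- splitDataset(df, splitSpec(c(1, 0, 0), seed = 1))
  expect_identical(nrow(all_train$train), 10L)
  expect_identical(nrow(all_train$test), 0L)
  expect_error(splitSpec(c(0.8, 0.1, 0.2)), "sum to 1")
  expect_error(splitDataset(df[1:2, , drop = FALSE], splitSpec()), "at least 3")
})
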