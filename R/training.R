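# ---------------------------------------------------------------------------
# Training loop (SGD with momentum, per-epoch validation, best-F1
# checkpointing), seeding, checkpoint serialization and sliding-window
# inference for micrographs larger than the training tile.
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' SGD with momentum over the combined BCE + Dice objective, with dropout
#' before the final classifier. Defaults follow the reference setup (up to
#' 1000 epochs, SGD, dropout 0.5); learning rate, momentum and batch size
#' are free choices exposed here.
#'
#' @param epochs maximum epochs (default 1000).
#' @param learningRate SGD step size (default 0.01).
#' @param momentum SGD momentum in [0, 1) (default 0.9).
#' @param weightDecay L2 penalty coefficient (default 0).
#' @param batchSize gradient-accumulation batch size (default 8).
#' @param dropoutP dropout probability (default 0.5).
#' @param seed integer seed controlling init order, shuffling and dropout.
#' @param earlyStopPatience stop after this many epochs without validation
#'   F1 improvement; `NULL` disables early stopping.
#' @param deepSupervision supervise the six side outputs (default `TRUE`).
#' @return Object of class `trainConfig`.
#' @export
trainConfig <- function(epochs = 1000L, learningRate = 0.01, momentum = 0.9,
                        weightDecay = 0, batchSize = 8L, dropoutP = 0.5,
                        seed = 1L, earlyStopPatience = NULL,
                        deepSupervision = TRUE) {
  stopifnot(epochs >= 1, learningRate >= 0, momentum >= 0, momentum < 1,
            weightDecay >= 0, batchSize >= 1, dropoutP >= 0, dropoutP < 1)
  structure(list(epochs = as.integer(epochs), optimizer = "sgd",
                 learningRate = learningRate, momentum = momentum,
                 weightDecay = weightDecay, batchSize = as.integer(batchSize),
                 dropoutP = dropoutP, seed = as.integer(seed),
                 earlyStopPatience = earlyStopPatience,
                 deepSupervision = isTRUE(deepSupervision)),
            class = "trainConfig")
}

#' Seed every source of randomness
#'
#' All stochastic operations in the package (weight init, augmentation,
#' shuffling, dropout, scene generation) draw from R's RNG; seeding it
#' makes them bit-reproducible.
#'
#' @param seed integer seed.
#' @return The seed, invisibly.
#' @export
setGlobalSeed <- function(seed) {
  set.seed(as.integer(seed))
  invisible(seed)
}

#' Train the segmentation network
#'
#' Minibatch SGD (gradient accumulation over single-sample passes) on the
#' combined BCE + Dice loss with deep supervision. After every epoch the
#' model is evaluated on the validation set (fused map, threshold 0.5) and
#' the parameter state with the best validation F1 is retained; that best
#' state is restored into the model before returning. A non-finite loss
#' aborts with the epoch and batch index.
#'
#' @param model an [ACU2Net-class]; its parameters are updated in place.
#' @param trainSet,valSet lists of [AnnotatedImage-class] tiles (sizes
#'   divisible by 32). `valSet = NULL` validates on the training set.
#' @param cfg a [trainConfig()].
#' @param verbose print a line per epoch.
#' @return List with `model`, `log` (one row per epoch: losses and
#'   validation Acc/Se/Sp/F1) and `checkpoint` (best parameter state with
#'   config and seed).
#' @export
trainModel <- function(model, trainSet, valSet = NULL, cfg = trainConfig(),
                       verbose = FALSE) {
  stopifnot(is(model, "ACU2Net"), inherits(cfg, "trainConfig"),
            length(trainSet) >= 1L)
  if (is.null(valSet)) valSet <- trainSet
  setGlobalSeed(cfg$seed)
  model@config$dropoutP <- cfg$dropoutP
  params <- model@modules$params
  state <- sgdState(params)
  n <- length(trainSet)
  targets <- lapply(trainSet, maskArray)
  valTargets <- lapply(valSet, maskArray)

  bestF1 <- -Inf; bestParams <- NULL; bestEpoch <- NA_integer_
  sinceBest <- 0L
  log <- vector("list", cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    epochLoss <- 0
    b0 <- 1L
    batchIdx <- 0L
    while (b0 <= n) {
      batch <- ord[b0:min(n, b0 + cfg$batchSize - 1L)]
      batchIdx <- batchIdx + 1L
      agZeroGrad(params)
      for (i in batch) {
        tp <- withTape({
          fwd <- acuForwardFull(model, trainSet[[i]], train = TRUE)
          trainingLossNode(fwd, targets[[i]],
                           deepSupervision = cfg$deepSupervision)
        })
        lv <- tp$result$v
        if (!is.finite(lv))
          stop("non-finite loss at epoch ", epoch, ", batch ", batchIdx,
               " (sample ", i, ")")
        epochLoss <- epochLoss + lv
        agBackward(tp$result, tp$tape)
      }
      for (p in params) if (!is.null(p$g)) p$g <- p$g / length(batch)
      state <- sgdStep(params, state, cfg$learningRate, cfg$momentum,
                       cfg$weightDecay)
      b0 <- b0 + cfg$batchSize
    }
    trainLoss <- epochLoss / n

    # validation: fused-map loss and thresholded metrics, pooled counts
    valLoss <- 0
    preds <- vector("list", length(valSet))
    for (j in seq_along(valSet)) {
      pm <- predictMaps(model, valSet[[j]])
      valLoss <- valLoss + bceLoss(pm$fused, valTargets[[j]]) +
        diceLoss(pm$fused, valTargets[[j]])
      preds[[j]] <- matrix(as.integer(pm$fused >= 0.5), nrow(pm$fused))
    }
    valLoss <- valLoss / length(valSet)
    vm <- suppressWarnings(datasetMetrics(preds, valTargets, "micro"))
    log[[epoch]] <- data.frame(epoch = epoch, train_loss = trainLoss,
                               val_loss = valLoss, val_Acc = vm[["Acc"]],
                               val_Se = vm[["Se"]], val_Sp = vm[["Sp"]],
                               val_F1 = vm[["F1"]])
    if (verbose)
      message(sprintf("epoch %d  train %.4f  val %.4f  F1 %.3f",
                      epoch, trainLoss, valLoss, vm[["F1"]]))
    f1 <- vm[["F1"]]
    if (is.finite(f1) && f1 > bestF1) {
      bestF1 <- f1; bestEpoch <- epoch; sinceBest <- 0L
      bestParams <- lapply(params, function(p) p$v)
    } else sinceBest <- sinceBest + 1L
    if (!is.null(cfg$earlyStopPatience) && sinceBest >= cfg$earlyStopPatience)
      break
  }

  if (!is.null(bestParams))
    for (nm in names(bestParams)) params[[nm]]$v <- bestParams[[nm]]
  ckpt <- list(config = model@config, params = lapply(params, function(p) p$v),
               seed = cfg$seed, bestEpoch = bestEpoch, bestValF1 = bestF1,
               configHash = configHash(model@config))
  list(model = model, log = do.call(rbind, log[!vapply(log, is.null, logical(1))]),
       checkpoint = ckpt)
}

# Cheap structural hash of a configuration (embedded in checkpoints and
# verified on load).
configHash <- function(cfg) {
  raw <- serialize(cfg, NULL, version = 2L)
  sprintf("%08x", sum(as.integer(raw) * (seq_along(raw) %% 251L)) %% 2^28)
}

#' Save / load a model checkpoint
#'
#' Checkpoints contain the resolved network configuration (with an embedded
#' hash), every parameter array, and the training seed. Loading rebuilds
#' the architecture from the stored configuration and restores the weights.
#'
#' @param checkpoint a checkpoint list (from [trainModel()]) or an
#'   [ACU2Net-class] model (its current weights are stored).
#' @param path file path (`.rds`).
#' @return `saveCheckpoint()` the path invisibly; `loadCheckpoint()` an
#'   [ACU2Net-class] model.
#' @export
saveCheckpoint <- function(checkpoint, path) {
  if (is(checkpoint, "ACU2Net"))
    checkpoint <- list(config = checkpoint@config,
                       params = lapply(checkpoint@modules$params,
                                       function(p) p$v),
                       seed = NA_integer_, bestEpoch = NA_integer_,
                       bestValF1 = NA_real_,
                       configHash = configHash(checkpoint@config))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$configHash, configHash(ck$config)))
    warning("checkpoint config hash mismatch; the file may be corrupted")
  cfg <- ck$config
  cfg$gcmGroups <- NULL
  class(cfg) <- "networkConfig"
  model <- acu2net(cfg)
  params <- model@modules$params
  stopifnot(identical(sort(names(params)), sort(names(ck$params))))
  for (nm in names(ck$params)) params[[nm]]$v <- ck$params[[nm]]
  model
}

# Reflect-pad an H x W x C array to at least (th, tw).
reflectPad <- function(arr, th, tw) {
  d <- dim(arr)
  if (d[1L] >= th && d[2L] >= tw) return(arr)
  ridx <- seq_len(max(th, d[1L]))
  ridx <- ifelse(ridx <= d[1L], ridx, 2L * d[1L] - ridx)  # reflect
  cidx <- seq_len(max(tw, d[2L]))
  cidx <- ifelse(cidx <= d[2L], cidx, 2L * d[2L] - cidx)
  if (any(ridx < 1L) || any(cidx < 1L))
    stop("image too small to reflect-pad to ", th, "x", tw)
  arr[ridx, cidx, , drop = FALSE]
}

#' Sliding-window inference on a full-size micrograph
#'
#' Tiles the image with a stride of `tile - overlap`, averages the fused
#' probability map over overlapping windows, and binarizes at `threshold`.
#' Images smaller than the tile are reflect-padded; the returned mask
#' always matches the input size.
#'
#' @param model an [ACU2Net-class].
#' @param image `H x W x 3` array or [AnnotatedImage-class].
#' @param tile window side, divisible by 32 (default 256).
#' @param overlap window overlap in pixels, `0 <= overlap < tile`.
#' @param threshold binarization threshold in (0, 1) (default 0.5).
#' @param returnProb also return the averaged probability map.
#' @return Integer `H x W` mask, or (with `returnProb`) a list
#'   `list(mask, prob)`.
#' @export
predictMask <- function(model, image, tile = 256L, overlap = 32L,
                        threshold = 0.5, returnProb = FALSE) {
  if (tile %% 32L != 0L) stop("tile must be divisible by 32")
  if (overlap < 0L || overlap >= tile) stop("need 0 <= overlap < tile")
  x <- normalizeInput(image)
  H <- dim(x)[1L]; W <- dim(x)[2L]
  xp <- reflectPad(x, tile, tile)
  Hp <- dim(xp)[1L]; Wp <- dim(xp)[2L]
  stride <- tile - overlap
  starts <- function(total) {
    s <- seq(1L, max(1L, total - tile + 1L), by = stride)
    if (s[length(s)] + tile - 1L < total) s <- c(s, total - tile + 1L)
    s
  }
  acc <- matrix(0, Hp, Wp); cnt <- matrix(0, Hp, Wp)
  for (r in starts(Hp)) for (c in starts(Wp)) {
    win <- xp[r:(r + tile - 1L), c:(c + tile - 1L), , drop = FALSE]
    pm <- predictMaps(model, win)
    acc[r:(r + tile - 1L), c:(c + tile - 1L)] <-
      acc[r:(r + tile - 1L), c:(c + tile - 1L)] + pm$fused
    cnt[r:(r + tile - 1L), c:(c + tile - 1L)] <-
      cnt[r:(r + tile - 1L), c:(c + tile - 1L)] + 1
  }
  prob <- (acc / cnt)[seq_len(H), seq_len(W), drop = FALSE]
  mask <- matrix(as.integer(prob >= threshold), H, W)
  if (returnProb) list(mask = mask, prob = prob) else mask
}
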