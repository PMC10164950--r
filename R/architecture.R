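# ---------------------------------------------------------------------------
# Backbone configuration and full-network assembly.
#
# The backbone is the six-encoder / five-decoder nested U-structure: encoder
# RSU levels 7,6,5,4 then two dilated RSU-4D stages, joined by 2x2 max
# pooling so the bottleneck feature is 1/32 of the input side; decoders
# mirror the encoders. Skip connections carry each encoder output to its
# mirror decoder, either by plain concatenation (plain-U2Net ablation) or
# through Grouping Cross Merge modules whose output has (Cs + Cd)/2
# channels -- which is exactly why the decoder input channel counts of the
# published parameter table come out as they do.
# ---------------------------------------------------------------------------

#' Backbone stage configuration
#'
#' Builds the 11-stage channel table of the nested U-structure. At
#' `widthScale = 1` the encoder output channels are 64, 128, 256, 512, 512,
#' 512 with mid channels 32, 32, 64, 128, 256, 256 (decoders mirrored,
#' decoder outputs 512, 256, 128, 64, 32); `widthScale < 1` shrinks every
#' count proportionally (rounded to multiples of 8 and 4) for desk-scale
#' models. The first encoder stage prints 64 output channels: the next
#' stage's 64-channel input forces that reading of the published table.
#'
#' @param widthScale positive scale factor on all channel counts.
#' @param inputChannels image channels (3 for RGB).
#' @return An object of class `backboneConfig`.
#' @export
backboneConfig <- function(widthScale = 1, inputChannels = 3L) {
  stopifnot(widthScale > 0)
  sc8 <- function(x) pmax(8L, as.integer(round(x * widthScale / 8) * 8))
  sc4 <- function(x) pmax(4L, as.integer(round(x * widthScale / 4) * 4))
  structure(list(
    inputChannels = as.integer(inputChannels),
    encOut = sc8(c(64, 128, 256, 512, 512, 512)),
    encMid = sc4(c(32, 32, 64, 128, 256, 256)),
    encL = c(7L, 6L, 5L, 4L, 4L, 4L),
    encDilated = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    # decoder rows ordered Decoder5 .. Decoder1
    decOut = sc8(c(512, 256, 128, 64, 32)),
    decMid = sc4(c(256, 128, 64, 32, 32)),
    decL = c(4L, 4L, 5L, 6L, 7L),
    decDilated = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    widthScale = widthScale
  ), class = "backboneConfig")
}

#' GCM skip-module configuration
#'
#' Group counts per skip depth. Shallow skips use few groups, deep skips
#' many: the defaults aim at n = 4 for the two shallowest skips, 6 for the
#' middle one and 8 for the two deepest. A group count must divide the
#' channel counts entering that skip; where the requested value does not
#' (the published power-of-two channel table is not divisible by 6), the
#' constructor substitutes the largest admissible value from 8, 6, 4, 2, 1
#' at assembly time.
#'
#' @param groupsByDepth integer vector of length 5, group counts for skips
#'   at Decoder1..Decoder5; `NULL` for the defaults `c(4, 4, 6, 8, 8)`.
#' @param serialLink logical; chain each GCM's output into the next
#'   shallower GCM (deep-to-shallow feature transfer channel).
#' @param strict logical; if `TRUE`, a non-dividing group count is an error
#'   instead of being substituted.
#' @return An object of class `gcmConfig`.
#' @export
gcmConfig <- function(groupsByDepth = NULL, serialLink = TRUE, strict = FALSE) {
  if (is.null(groupsByDepth)) groupsByDepth <- c(4L, 4L, 6L, 8L, 8L)
  stopifnot(length(groupsByDepth) == 5L, all(groupsByDepth >= 1))
  structure(list(groupsByDepth = as.integer(groupsByDepth),
                 serialLink = isTRUE(serialLink), strict = isTRUE(strict)),
            class = "gcmConfig")
}

#' RAG configuration
#'
#' @param reductionRatio bottleneck reduction ratio r of the channel
#'   attention (the hidden layer has `c / r` units, clamped to at least 4).
#' @param interChannels channels of the fused feature space; `NULL` uses the
#'   channel count of the skip feature x.
#' @return An object of class `ragConfig`.
#' @export
ragConfig <- function(reductionRatio = 16L, interChannels = NULL) {
  stopifnot(reductionRatio >= 1)
  structure(list(reductionRatio = as.integer(reductionRatio),
                 interChannels = interChannels), class = "ragConfig")
}

#' Full network configuration
#'
#' Combines backbone, GCM and RAG settings with the classifier options. The
#' four ablation variants are reachable through `useGCM` / `useRAG` (plain
#' U2Net has both off). `fusionMode` selects how the final map is formed
#' from the splice of the six side outputs and the RAG-classifier branch:
#' `"average"` (mean of the two logit maps, the default), `"splice"` (side
#' outputs only) or `"rag"` (attention branch only). With `useRAG = FALSE`
#' the splice is always used.
#'
#' @param backbone a [backboneConfig()].
#' @param gcm a [gcmConfig()].
#' @param rag a [ragConfig()].
#' @param dropoutP dropout probability before the final 1x1 classifier.
#' @param useGCM,useRAG logical module switches.
#' @param fusionMode `"average"`, `"splice"` or `"rag"`.
#' @return An object of class `networkConfig`.
#' @export
networkConfig <- function(backbone = backboneConfig(), gcm = gcmConfig(),
                          rag = ragConfig(), dropoutP = 0.5,
                          useGCM = TRUE, useRAG = TRUE,
                          fusionMode = c("average", "splice", "rag")) {
  stopifnot(inherits(backbone, "backboneConfig"), inherits(gcm, "gcmConfig"),
            inherits(rag, "ragConfig"), dropoutP >= 0, dropoutP < 1)
  fusionMode <- match.arg(fusionMode)
  structure(list(backbone = backbone, gcm = gcm, rag = rag,
                 dropoutP = dropoutP, useGCM = isTRUE(useGCM),
                 useRAG = isTRUE(useRAG), fusionMode = fusionMode,
                 sideOutputs = 6L), class = "networkConfig")
}

# Resolve the effective group count for one skip: largest admissible value
# not exceeding the requested one if the request does not divide.
resolveGroups <- function(n, cs, cd, strict, stage) {
  if (cs %% n == 0L && cd %% n == 0L && ((cs + cd) / n) %% 2L == 0L) return(n)
  if (strict)
    stop("GCM at ", stage, ": n=", n, " does not divide channels (",
         cs, ", ", cd, ")")
  for (cand in c(8L, 6L, 4L, 2L, 1L)) {
    if (cand <= n && cs %% cand == 0L && cd %% cand == 0L &&
        ((cs + cd) / cand) %% 2L == 0L) return(cand)
  }
  stop("GCM at ", stage, ": no admissible group count for channels (",
       cs, ", ", cd, ")")
}

#' Write / read a network configuration as YAML
#'
#' Serializes the constructor arguments of a [networkConfig()] (backbone
#' width scale, GCM group counts and serial link, RAG reduction ratio,
#' dropout, module switches, fusion mode) to a YAML file and back.
#'
#' @param cfg a [networkConfig()].
#' @param path YAML file path.
#' @return `writeNetworkConfig()` the path invisibly; `readNetworkConfig()`
#'   a [networkConfig()].
#' @export
writeNetworkConfig <- function(cfg, path) {
  stopifnot(inherits(cfg, "networkConfig") || is.list(cfg))
  yaml::write_yaml(list(
    backbone = list(widthScale = cfg$backbone$widthScale,
                    inputChannels = cfg$backbone$inputChannels),
    gcm = list(groupsByDepth = cfg$gcm$groupsByDepth,
               serialLink = cfg$gcm$serialLink, strict = cfg$gcm$strict),
    rag = list(reductionRatio = cfg$rag$reductionRatio,
               interChannels = cfg$rag$interChannels),
    dropoutP = cfg$dropoutP, useGCM = cfg$useGCM, useRAG = cfg$useRAG,
    fusionMode = cfg$fusionMode), path)
  invisible(path)
}

#' @rdname writeNetworkConfig
#' @export
readNetworkConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  networkConfig(
    backbone = backboneConfig(y$backbone$widthScale %||% 1,
                              y$backbone$inputChannels %||% 3L),
    gcm = gcmConfig(y$gcm$groupsByDepth, isTRUE(y$gcm$serialLink),
                    isTRUE(y$gcm$strict)),
    rag = ragConfig(y$rag$reductionRatio %||% 16L, y$rag$interChannels),
    dropoutP = y$dropoutP %||% 0.5,
    useGCM = isTRUE(y$useGCM), useRAG = isTRUE(y$useRAG),
    fusionMode = y$fusionMode %||% "average")
}

#' Assemble the segmentation network
#'
#' Builds every module of the network from a [networkConfig()]: encoder and
#' decoder RSUs, GCM skip modules (serially linked deep-to-shallow), the
#' RAG on the shallowest skip, six side-output heads, the splice head and
#' the RAG classifier. Weights are He-uniform, drawn from the current RNG
#' state (use [setGlobalSeed()] or `seed` for reproducible builds); the
#' parameter count is a pure function of the configuration.
#'
#' @param cfg a [networkConfig()].
#' @param seed optional integer seed for weight initialization.
#' @return An [ACU2Net-class] model object.
#' @export
acu2net <- function(cfg = networkConfig(), seed = NULL) {
  stopifnot(inherits(cfg, "networkConfig"))
  if (!is.null(seed)) set.seed(seed)
  bb <- cfg$backbone
  mod <- new.env(parent = emptyenv())

  # encoders
  encIn <- c(bb$inputChannels, bb$encOut[1:5])
  mod$enc <- lapply(1:6, function(k)
    rsuBlock(rsuConfig(bb$encL[k], encIn[k], bb$encMid[k], bb$encOut[k],
                       dilated = bb$encDilated[k])))

  # skip channel bookkeeping: at skip k (Decoder k), shallow = encoder k
  # output, deep = output of the next-deeper decoder (encoder 6 for k = 5).
  deepCh <- numeric(5)
  deepCh[5L] <- bb$encOut[6L]                 # into Decoder5: Encoder6 output
  for (k in 4:1) deepCh[k] <- bb$decOut[6L - (k + 1L)]  # Decoder(k+1) output
  shallowCh <- bb$encOut[1:5]

  gcmGroups <- integer(5)
  if (cfg$useGCM) {
    mod$gcm <- vector("list", 5L)
    for (k in 5:1) {
      n <- resolveGroups(cfg$gcm$groupsByDepth[k], shallowCh[k], deepCh[k],
                         cfg$gcm$strict, paste0("skip", k))
      gcmGroups[k] <- n
      carry <- if (cfg$gcm$serialLink && k < 5L) (shallowCh[k + 1L] + deepCh[k + 1L]) %/% 2L else NULL
      mod$gcm[[k]] <- gcmBlock(shallowCh[k], deepCh[k], n, carry,
                               stage = paste0("skip", k))
    }
  }

  # decoders (stored De5..De1 as in the channel table)
  skipOutCh <- if (cfg$useGCM) (shallowCh + deepCh) %/% 2L else shallowCh + deepCh
  mod$dec <- lapply(1:5, function(i) {   # i = 1 -> Decoder5 ... i = 5 -> Decoder1
    k <- 6L - i
    rsuBlock(rsuConfig(bb$decL[i], skipOutCh[k], bb$decMid[i], bb$decOut[i],
                       dilated = bb$decDilated[i]))
  })

  # side-output heads: Encoder6 then Decoder5..Decoder1 (3x3 conv to 1 ch)
  sideCh <- c(bb$encOut[6L], bb$decOut)
  mod$side <- lapply(sideCh, function(cc) agInitConv(cc, 1L, 3L))
  mod$fuse <- agInitConv(6L, 1L, 1L)

  if (cfg$useRAG) {
    cx <- skipOutCh[1L]            # shallowest skip feature entering Decoder1
    cg <- bb$decOut[4L]            # Decoder2 output (half resolution)
    mod$rag <- ragBlock(cx, cg, cfg$rag$reductionRatio, cfg$rag$interChannels)
    mod$ragCls <- agInitConv(mod$rag$interChannels, 1L, 1L)
  }

  cfg$gcmGroups <- gcmGroups
  mod$params <- collectParams(list(enc = mod$enc, dec = mod$dec,
                                   gcm = if (cfg$useGCM) lapply(mod$gcm, `[[`, "params"),
                                   side = mod$side, fuse = mod$fuse,
                                   rag = if (cfg$useRAG) mod$rag$params,
                                   ragCls = if (cfg$useRAG) mod$ragCls),
                              prefix = "net")
  new("ACU2Net", config = unclass(cfg), modules = mod)
}

# Normalize an input image to an H x W x 3 array in [0, 1].
normalizeInput <- function(image) {
  if (inherits(image, "AnnotatedImage")) image <- imageArray(image)
  if (is.matrix(image)) image <- array(rep(image, 3L), c(dim(image), 3L))
  image <- array(as.numeric(image), dim(image))
  if (max(image) > 1) image <- image / 255
  image
}

# Full forward pass; returns stage nodes, side logit/prob nodes and the
# fused map node. Everything downstream (losses, prediction, inspection)
# goes through here.
acuForwardFull <- function(model, image, train = FALSE) {
  cfg <- model@config
  mod <- model@modules
  x <- normalizeInput(image)
  H <- dim(x)[1L]; W <- dim(x)[2L]
  if (H %% 32L != 0L || W %% 32L != 0L)
    stop("input size ", H, "x", W, " must be divisible by 32 ",
         "(five 2x2 pooling stages)")
  xin <- agConst(x)

  encOuts <- vector("list", 6L)
  h <- xin
  for (k in 1:6) {
    encOuts[[k]] <- mod$enc[[k]]$forward(h)
    if (k < 6L) h <- agMaxPool2(encOuts[[k]])
  }

  decOuts <- vector("list", 5L)   # [k] = Decoder k output
  skipFeats <- vector("list", 5L)
  deep <- encOuts[[6L]]
  carry <- NULL
  for (k in 5:1) {
    dE <- dim(encOuts[[k]]$v)
    deepUp <- agResize(deep, dE[1L], dE[2L])
    if (cfg$useGCM) {
      skipFeats[[k]] <- mod$gcm[[k]]$forward(encOuts[[k]], deepUp,
        carry = if (cfg$gcm$serialLink) carry else NULL)
      carry <- skipFeats[[k]]
    } else {
      skipFeats[[k]] <- agConcat(list(deepUp, encOuts[[k]]))
    }
    decOuts[[k]] <- mod$dec[[6L - k]]$forward(skipFeats[[k]])
    deep <- decOuts[[k]]
  }

  # six side outputs: Encoder6, Decoder5..Decoder1, logits at input size
  sideSrc <- c(encOuts[6L], decOuts[5:1])
  sideLogits <- vector("list", 6L)
  for (i in 1:6) {
    s <- mod$side[[i]]
    sideLogits[[i]] <- agResize(agConv(sideSrc[[i]], s$w, s$b, 3L), H, W)
  }
  spliceLogits <- agConv(agConcat(sideLogits), mod$fuse$w, mod$fuse$b, 1L)

  ragLogits <- NULL
  attention <- NULL
  if (cfg$useRAG) {
    rr <- mod$rag$forward(skipFeats[[1L]], decOuts[[2L]], return_attention = TRUE)
    attention <- rr$attention
    rdrop <- agDropout(rr$out, cfg$dropoutP)
    ragLogits <- agConv(rdrop, mod$ragCls$w, mod$ragCls$b, 1L)
  }

  fusedLogits <- if (!cfg$useRAG || cfg$fusionMode == "splice") {
    spliceLogits
  } else if (cfg$fusionMode == "rag") {
    ragLogits
  } else {
    agScale(agAdd(spliceLogits, ragLogits), 0.5)
  }

  stages <- c(encOuts, decOuts[5:1])
  names(stages) <- c(paste0("Encoder", 1:6), paste0("Decoder", 5:1))
  list(stages = stages,
       sideLogits = sideLogits,
       sideProbs = lapply(sideLogits, agSigmoid),
       fused = agSigmoid(fusedLogits),
       attention = attention)
}

#' Run the backbone and return every stage feature
#'
#' Executes a full forward pass on one image and returns the 11 stage
#' outputs (Encoder1..Encoder6, Decoder5..Decoder1) as plain `H x W x C`
#' arrays. Input height and width must be divisible by 32.
#'
#' @param model an [ACU2Net-class] model.
#' @param image `H x W x 3` array (0..255 or 0..1) or [AnnotatedImage-class].
#' @return Named list of stage feature arrays.
#' @export
forwardBackbone <- function(model, image) {
  out <- withNoGrad(acuForwardFull(model, image))
  lapply(out$stages, function(n) n$v)
}

#' Forward pass returning the probability maps
#'
#' @param model an [ACU2Net-class] model.
#' @param image `H x W x 3` array or [AnnotatedImage-class].
#' @return List with `fused` (`H x W` matrix of probabilities in (0,1)),
#'   `side` (list of six `H x W` side-output probability maps, ordered
#'   O6..O1), and `attention` (the RAG channel weights, or `NULL`).
#' @export
predictMaps <- function(model, image) {
  out <- withNoGrad(acuForwardFull(model, image))
  list(fused = out$fused$v[, , 1L],
       side = lapply(out$sideProbs, function(n) n$v[, , 1L]),
       attention = if (!is.null(out$attention)) out$attention$v)
}

#' Number of trainable parameters
#'
#' @param model an [ACU2Net-class] model.
#' @return Integer parameter count (a pure function of the configuration).
#' @export
countParams <- function(model) {
  sum(vapply(model@modules$params, function(p) length(p$v), numeric(1)))
}

#' Stage table of the assembled network
#'
#' Analytic per-stage input/output shapes (for a given input size) plus
#' parameter counts, in the layout of the published network-parameter table.
#'
#' @param model an [ACU2Net-class] model.
#' @param inputSize height/width of the notional input (divisible by 32).
#' @return A data.frame with columns stage, block, input, output, params.
#' @export
stageTable <- function(model, inputSize = 256L) {
  cfg <- model@config; bb <- cfg$backbone
  side <- inputSize / 2^(0:5)
  encIn <- c(bb$inputChannels, bb$encOut[1:5])
  rows <- data.frame(
    stage = c(paste0("Encoder", 1:6), paste0("Decoder", 5:1)),
    block = c(sprintf("RSU-%d%s", bb$encL, ifelse(bb$encDilated, "D", "")),
              sprintf("RSU-%d%s", bb$decL, ifelse(bb$decDilated, "D", ""))),
    input = c(sprintf("%dx%dx%d", encIn, side, side),
              sprintf("%dx%dx%d",
                      if (cfg$useGCM) (bb$encOut[5:1] + c(bb$encOut[6L], bb$decOut[1:4])) %/% 2L
                      else bb$encOut[5:1] + c(bb$encOut[6L], bb$decOut[1:4]),
                      side[5:1], side[5:1])),
    output = c(sprintf("%dx%dx%d", bb$encOut, side, side),
               sprintf("%dx%dx%d", bb$decOut, side[5:1], side[5:1])),
    stringsAsFactors = FALSE)
  nparam <- function(m) sum(vapply(collectParams(m$params), function(p) length(p$v), numeric(1)))
  rows$params <- c(vapply(model@modules$enc, nparam, numeric(1)),
                   vapply(model@modules$dec, nparam, numeric(1)))
  rows
}
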