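# ---------------------------------------------------------------------------
# Training objective: binary cross-entropy plus soft Dice, applied to the
# fused map and (deep supervision) to each of the six side outputs.
# ---------------------------------------------------------------------------

checkSameShape <- function(a, b) {
  if (!identical(dim(a), dim(b)) &&
      !(is.null(dim(a)) && is.null(dim(b)) && length(a) == length(b)))
    stop("prediction and target shapes differ: ",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"))
}

#' Binary cross-entropy loss
#'
#' Mean pixelwise binary cross-entropy
#' `-(1/n) * sum(y * log(x) + (1 - y) * log(1 - x))` between a probability
#' map and a binary target. Predictions are clamped to `[eps, 1 - eps]`
#' before the logarithms.
#'
#' @param pred numeric array of probabilities.
#' @param target binary array of the same shape.
#' @param eps clamping constant (default 1e-7).
#' @return Nonnegative scalar loss.
#' @export
bceLoss <- function(pred, target, eps = 1e-7) {
  checkSameShape(pred, target)
  p <- pmin(pmax(as.numeric(pred), eps), 1 - eps)
  y <- as.numeric(target)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(pred * target) + smooth) / (sum(pred) + sum(target) +
#' smooth)`: the complement of the (smoothed) Dice overlap coefficient,
#' 0 for perfect binary overlap and 1 for disjoint binary maps as
#' `smooth -> 0`.
#'
#' @param pred numeric array of probabilities.
#' @param target binary array of the same shape.
#' @param smooth smoothing constant (default 1).
#' @return Scalar loss in `[0, 1]`.
#' @export
diceLoss <- function(pred, target, smooth = 1) {
  checkSameShape(pred, target)
  stopifnot(smooth >= 0)
  p <- as.numeric(pred); y <- as.numeric(target)
  1 - (2 * sum(p * y) + smooth) / (sum(p) + sum(y) + smooth)
}

#' Combined BCE + Dice objective over all output maps
#'
#' Applies [bceLoss()] + [diceLoss()] to the fused map and, under deep
#' supervision, to each of the six side-output maps; the total is the sum
#' over supervised maps. The fused map's own breakdown is reported
#' separately.
#'
#' @param outputs list with elements `fused` (probability map) and `side`
#'   (list of six side-output probability maps), as returned by
#'   [predictMaps()].
#' @param target binary map of the same shape.
#' @param deepSupervision include the six side outputs (default `TRUE`).
#' @param smooth,eps loss constants, see [diceLoss()] and [bceLoss()].
#' @return List with `bce`, `dice`, `total` (sums over supervised maps,
#'   `total = bce + dice`) and `fused`, the fused map's own `bce`/`dice`.
#' @export
combinedLoss <- function(outputs, target, deepSupervision = TRUE,
                         smooth = 1, eps = 1e-7) {
  maps <- list(outputs$fused)
  if (isTRUE(deepSupervision)) maps <- c(maps, outputs$side)
  bces <- vapply(maps, bceLoss, numeric(1), target = target, eps = eps)
  dices <- vapply(maps, diceLoss, numeric(1), target = target, smooth = smooth)
  list(bce = sum(bces), dice = sum(dices), total = sum(bces) + sum(dices),
       fused = list(bce = bces[1L], dice = dices[1L]))
}

# Graph version used by the training loop: same objective expressed on
# autodiff nodes so gradients flow to every supervised head.
trainingLossNode <- function(fwd, target, deepSupervision = TRUE,
                             smooth = 1, eps = 1e-7) {
  tgt <- array(as.numeric(target), c(dim(target)[1L], dim(target)[2L], 1L))
  maps <- list(fwd$fused)
  if (isTRUE(deepSupervision)) maps <- c(maps, fwd$sideProbs)
  terms <- vector("list", 2L * length(maps))
  for (i in seq_along(maps)) {
    terms[[2L * i - 1L]] <- agBce(maps[[i]], tgt, eps)
    terms[[2L * i]] <- agDice(maps[[i]], tgt, smooth)
  }
  agSumScalars(terms)
}
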