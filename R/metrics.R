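# ---------------------------------------------------------------------------
# Pixel-confusion evaluation: TP/FP/TN/FN tallies and the four derived
# scores (accuracy, sensitivity, specificity, F1).
# ---------------------------------------------------------------------------

#' Pixel confusion counts
#'
#' Tallies true/false positives and negatives between a predicted and a
#' reference binary mask. Both inputs must be strictly binary; the four
#' counts always sum to the number of evaluated pixels.
#'
#' @param pred,truth binary matrices/arrays of identical shape.
#' @return Object of class `confusionCounts`: list with `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
confusionCounts <- function(pred, truth) {
  checkSameShape(pred, truth)
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("confusionCounts() requires strictly binary masks")
  p <- as.integer(pred); y <- as.integer(truth)
  structure(list(TP = sum(p == 1L & y == 1L), FP = sum(p == 1L & y == 0L),
                 TN = sum(p == 0L & y == 0L), FN = sum(p == 0L & y == 1L)),
            class = "confusionCounts")
}

#' Segmentation metrics from confusion counts
#'
#' Computes accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)` and F1 `2TP/(2TP+FP+FN)`. A zero denominator yields `NaN`
#' for that metric, with a warning -- degenerate cases are surfaced, never
#' silently mapped to 0 or 1.
#'
#' @param counts a `confusionCounts` object, or a list/vector with elements
#'   TP, FP, TN, FN.
#' @return Named numeric vector `c(Acc, Se, Sp, F1)`.
#' @export
segMetrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  total <- tp + fp + tn + fn
  if (total == 0) stop("no pixels to evaluate")
  safe <- function(num, den, what) {
    if (den == 0) {
      warning("undefined ", what, " (zero denominator); reporting NaN",
              call. = FALSE)
      return(NaN)
    }
    num / den
  }
  c(Acc = (tp + tn) / total,
    Se = safe(tp, tp + fn, "sensitivity"),
    Sp = safe(tn, tn + fp, "specificity"),
    F1 = safe(2 * tp, 2 * tp + fp + fn, "F1"))
}

#' Dataset-level metrics over many mask pairs
#'
#' Micro-averaging (the default) pools confusion counts over all images and
#' derives one set of scores, matching a single-number-per-model
#' presentation; macro-averaging scores each image and averages the scores.
#'
#' @param preds,truths lists of binary masks of matching shapes.
#' @param average `"micro"` or `"macro"`.
#' @return Named numeric vector `c(Acc, Se, Sp, F1)`; for micro-averaging
#'   the pooled counts are attached as attribute `"counts"`.
#' @export
datasetMetrics <- function(preds, truths, average = c("micro", "macro")) {
  average <- match.arg(average)
  stopifnot(length(preds) == length(truths), length(preds) >= 1L)
  cs <- Map(confusionCounts, preds, truths)
  if (average == "micro") {
    pooled <- structure(list(TP = sum(vapply(cs, `[[`, numeric(1), "TP")),
                             FP = sum(vapply(cs, `[[`, numeric(1), "FP")),
                             TN = sum(vapply(cs, `[[`, numeric(1), "TN")),
                             FN = sum(vapply(cs, `[[`, numeric(1), "FN"))),
                        class = "confusionCounts")
    m <- segMetrics(pooled)
    attr(m, "counts") <- pooled
    m
  } else {
    per <- vapply(cs, segMetrics, numeric(4))
    rowMeans(per)
  }
}
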