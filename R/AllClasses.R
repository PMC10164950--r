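#' @import methods
#' @importFrom S4Vectors metadata
NULL

#' AnnotatedImage: a micrograph with its pixel-level ground truth
#'
#' Container for one brightfield organoid image, its binary segmentation
#' mask and acquisition metadata. The image is an `H x W x 3` array of 8-bit
#' intensities (stored as integers in 0..255); the mask is an `H x W`
#' integer matrix with 1 marking organoid pixels. Metadata carries at least
#' `source_id`, `culture_day` (integer >= 1), `group_label` (e.g. `"CTR"`,
#' `"RA"`, `"B0107"`) and `pixel_size_um` (default 1).
#'
#' @slot image integer array, `H x W x 3`, values in 0..255.
#' @slot mask integer matrix, `H x W`, values in {0, 1}.
#' @slot meta named list of metadata.
#' @export
setClass("AnnotatedImage",
  representation(image = "array", mask = "matrix", meta = "list"))

setValidity("AnnotatedImage", function(object) {
  di <- dim(object@image); dm <- dim(object@mask)
  msgs <- character()
  if (length(di) != 3L || di[3L] != 3L)
    msgs <- c(msgs, "image must be an H x W x 3 array")
  else if (!all(di[1:2] == dm))
    msgs <- c(msgs, "image and mask must share height and width")
  if (anyNA(object@image) || min(object@image) < 0 || max(object@image) > 255)
    msgs <- c(msgs, "image intensities must lie in 0..255")
  if (!all(object@mask %in% c(0L, 1L)))
    msgs <- c(msgs, "mask values must be 0 or 1")
  m <- object@meta
  if (!is.null(m$culture_day) && (!is.numeric(m$culture_day) || m$culture_day < 1))
    msgs <- c(msgs, "culture_day must be an integer >= 1")
  if (!is.null(m$pixel_size_um) && (!is.numeric(m$pixel_size_um) || m$pixel_size_um <= 0))
    msgs <- c(msgs, "pixel_size_um must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Construct an AnnotatedImage
#'
#' @param image numeric or integer `H x W x 3` array in 0..255 (an `H x W`
#'   matrix is expanded to three identical channels).
#' @param mask integer `H x W` matrix in {0, 1}; defaults to all background.
#' @param source_id identifier of the source micrograph.
#' @param culture_day integer culture day (>= 1).
#' @param group_label treatment group label.
#' @param pixel_size_um physical pixel edge length in micrometres.
#' @param meta additional metadata entries (named list), merged in.
#' @return An [AnnotatedImage-class] object.
#' @export
AnnotatedImage <- function(image, mask = NULL, source_id = "img",
                           culture_day = 1L, group_label = "CTR",
                           pixel_size_um = 1.0, meta = list()) {
  if (is.matrix(image)) image <- array(rep(image, 3L), c(dim(image), 3L))
  storage.mode(image) <- "integer"
  if (is.null(mask)) mask <- matrix(0L, dim(image)[1L], dim(image)[2L])
  storage.mode(mask) <- "integer"
  m <- utils::modifyList(
    list(source_id = source_id, culture_day = as.integer(culture_day),
         group_label = group_label, pixel_size_um = pixel_size_um),
    meta)
  new("AnnotatedImage", image = image, mask = mask, meta = m)
}

setMethod("show", "AnnotatedImage", function(object) {
  d <- dim(object@image)
  cat("AnnotatedImage ", d[1L], "x", d[2L], " (", object@meta$source_id, ")\n",
      sep = "")
  cat("  foreground: ", sum(object@mask), " px (",
      sprintf("%.1f%%", 100 * mean(object@mask)), ")\n", sep = "")
  cat("  day ", object@meta$culture_day, ", group ", object@meta$group_label,
      ", pixel size ", object@meta$pixel_size_um, " um\n", sep = "")
})

#' ACU2Net: the assembled segmentation network
#'
#' Holds the full attention-and-cross U2Net model: a six-encoder /
#' five-decoder backbone of residual U-blocks, Grouping Cross Merge modules
#' on the skip connections (serially linked deep-to-shallow), a Residual
#' Attention Gate on the shallowest skip, six side-output heads and the
#' fusion head. Parameters live in an environment so training updates in
#' place.
#'
#' @slot config the resolved [networkConfig()] list.
#' @slot modules environment holding the module tree and flat parameter list.
#' @export
setClass("ACU2Net",
  representation(config = "list", modules = "environment"))

setMethod("show", "ACU2Net", function(object) {
  cfg <- object@config
  cat("ACU2Net segmentation network\n")
  cat("  GCM skips: ", if (cfg$useGCM) paste0("on (n = ",
      paste(cfg$gcmGroups, collapse = "/"), " at skips 1..5)") else "off",
      "\n", sep = "")
  cat("  RAG: ", if (cfg$useRAG) "on" else "off",
      "; fusion mode: ", cfg$fusionMode,
      "; dropout p = ", cfg$dropoutP, "\n", sep = "")
  cat("  parameters: ", format(countParams(object), big.mark = ","), "\n", sep = "")
  tb <- stageTable(object)
  print(tb, row.names = FALSE)
})
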