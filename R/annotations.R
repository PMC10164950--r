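# ---------------------------------------------------------------------------
# Polygon annotations (Labelme-dialect JSON), rasterization to binary masks,
# and image/mask file I/O.
# ---------------------------------------------------------------------------

#' Polygon annotation set
#'
#' A set of labelled polygons over one image, in pixel coordinates
#' (0-based, origin top-left, x = column). Every polygon needs at least
#' three vertices, all inside `[0, width) x [0, height)`.
#'
#' @param shapes list of shapes, each a list with `label` (string) and
#'   `points` (n x 2 matrix of (x, y) vertices).
#' @param imageHeight,imageWidth canvas size in pixels.
#' @return Object of class `polygonAnnotation`.
#' @export
polygonAnnotation <- function(shapes, imageHeight, imageWidth) {
  stopifnot(imageHeight >= 1, imageWidth >= 1)
  shapes <- lapply(shapes, function(s) {
    pts <- s$points
    if (is.data.frame(pts)) pts <- as.matrix(pts)
    if (!is.matrix(pts)) pts <- do.call(rbind, pts)
    storage.mode(pts) <- "double"
    if (nrow(pts) < 3L)
      stop("polygon '", s$label %||% "?", "' has fewer than 3 vertices")
    if (any(pts[, 1L] < 0 | pts[, 1L] >= imageWidth |
            pts[, 2L] < 0 | pts[, 2L] >= imageHeight))
      stop("polygon '", s$label %||% "?", "' has vertices outside the canvas")
    list(label = s$label %||% "organoid", points = pts)
  })
  structure(list(shapes = shapes, imageHeight = as.integer(imageHeight),
                 imageWidth = as.integer(imageWidth)),
            class = "polygonAnnotation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a Labelme-dialect polygon annotation
#'
#' Parses the JSON produced by polygon annotation tools (keys
#' `shapes[].points`, `imageHeight`, `imageWidth`).
#'
#' @param path path to the JSON file.
#' @return A [polygonAnnotation()].
#' @export
readLabelme <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  j <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (is.null(j$imageHeight) || is.null(j$imageWidth))
    stop("missing imageHeight/imageWidth in ", path)
  shapes <- lapply(j$shapes, function(s)
    list(label = s$label, points = do.call(rbind, lapply(s$points, as.numeric))))
  polygonAnnotation(shapes, j$imageHeight, j$imageWidth)
}

#' Rasterize polygons to a binary mask
#'
#' A pixel is foreground iff its center lies inside or on the boundary of
#' any polygon (pixel centers at integer coordinates, 0-based, x = column);
#' overlapping polygons union.
#'
#' @param ann a [polygonAnnotation()].
#' @return Integer `H x W` matrix in {0, 1}.
#' @export
rasterizePolygons <- function(ann) {
  stopifnot(inherits(ann, "polygonAnnotation"))
  h <- ann$imageHeight; w <- ann$imageWidth
  mask <- matrix(0L, h, w)
  for (s in ann$shapes) {
    pts <- s$points
    cmin <- max(0L, floor(min(pts[, 1L]))); cmax <- min(w - 1L, ceiling(max(pts[, 1L])))
    rmin <- max(0L, floor(min(pts[, 2L]))); rmax <- min(h - 1L, ceiling(max(pts[, 2L])))
    if (cmin > cmax || rmin > rmax) next
    cols <- cmin:cmax; rows <- rmin:rmax
    gx <- rep(cols, each = length(rows))
    gy <- rep(rows, times = length(cols))
    inside <- pracma::inpolygon(gx, gy, pts[, 1L], pts[, 2L], boundary = TRUE)
    sub <- matrix(as.integer(inside), length(rows), length(cols))
    mask[rows + 1L, cols + 1L] <- pmax(mask[rows + 1L, cols + 1L], sub)
  }
  mask
}

# --- image and mask files ---------------------------------------------------

#' Read an image file
#'
#' Reads PNG/TIFF/JPEG micrographs into an `H x W x 3` integer array with
#' 8-bit intensities; grayscale images are expanded to three channels,
#' alpha channels dropped.
#'
#' @param path image file path.
#' @return Integer `H x W x 3` array in 0..255.
#' @export
readImageFile <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  im <- tryCatch(EBImage::readImage(path),
                 error = function(e) stop("cannot read image ", path, ": ",
                                          conditionMessage(e)))
  a <- EBImage::imageData(im)   # x (col) major
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3L] > 3L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3L] < 3L) a <- array(rep(a[, , 1L], 3L), c(dim(a)[1:2], 3L))
  out <- aperm(a, c(2L, 1L, 3L))   # -> H x W x 3
  out <- round(out * 255)
  storage.mode(out) <- "integer"
  out
}

#' Write / read a binary mask as single-channel PNG
#'
#' Masks are stored as 8-bit grayscale PNG with 0/255 on disk and mapped to
#' 0/1 in memory; the round trip is lossless.
#'
#' @param mask integer `H x W` matrix in {0, 1}.
#' @param path output (input) file path.
#' @return `writeMask()` the path invisibly; `readMask()` an integer matrix
#'   in {0, 1}.
#' @export
writeMask <- function(mask, path) {
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  if (!all(mask %in% c(0L, 1L))) stop("mask must be binary")
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  a <- tryCatch(png::readPNG(path),
                error = function(e) stop("cannot read mask ", path, ": ",
                                         conditionMessage(e)))
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  m <- matrix(as.integer(a > 0.5), nrow(a), ncol(a))
  m
}

# --- dataset manifests ------------------------------------------------------

#' Write / read a dataset manifest
#'
#' Manifests are plain CSV files with one row per image tile and columns
#' `path`, `mask_path`, `source_id`, `split`, `culture_day`, `group_label`,
#' `pixel_size_um`.
#'
#' @param manifest a data.frame with the columns above (missing ones are
#'   filled with defaults).
#' @param path CSV file path.
#' @return `writeManifest()` the path invisibly; `readManifest()` the
#'   data.frame.
#' @export
writeManifest <- function(manifest, path) {
  need <- c("path", "mask_path", "source_id", "split", "culture_day",
            "group_label", "pixel_size_um")
  defaults <- list(path = NA_character_, mask_path = NA_character_,
                   source_id = NA_character_, split = NA_character_,
                   culture_day = 1L, group_label = "CTR", pixel_size_um = 1.0)
  for (cc in need) if (is.null(manifest[[cc]])) manifest[[cc]] <- defaults[[cc]]
  utils::write.csv(manifest[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
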