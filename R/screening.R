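# ---------------------------------------------------------------------------
# Drug-screening quantification: per-organoid areas from predicted masks,
# grouped medians/quartiles by treatment and culture day, violin-plot data
# export, and the synthetic drug-effect fixture used to exercise the
# pipeline end to end.
# ---------------------------------------------------------------------------

#' Label connected foreground components
#'
#' Maximal connected foreground regions under 4- or 8-connectivity receive
#' distinct positive labels (background 0); components smaller than
#' `minSize` pixels are removed and remaining labels renumbered compactly.
#' Touching organoids merge into one component: no watershed splitting is
#' attempted.
#'
#' @param mask binary integer matrix.
#' @param connectivity 4 or 8 (default 8; organoid blobs are compact).
#' @param minSize minimum component area in pixels (default 30, a speckle
#'   filter at 256 x 256 tile scale).
#' @return List with `labels` (integer matrix) and `count`.
#' @export
labelComponents <- function(mask, connectivity = 8L, minSize = 30L) {
  if (!all(mask %in% c(0L, 1L))) stop("labelComponents() requires a binary mask")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  m <- mask; storage.mode(m) <- "integer"
  lab <- cpp_label_components(m, as.integer(connectivity), as.integer(minSize))
  list(labels = lab, count = attr(lab, "n_components"))
}

#' Measure per-organoid areas and centroids
#'
#' One record per labelled component: exact pixel count, physical area
#' (`area_pixels * pixel_size_um^2`), centroid (mean pixel coordinates,
#' 1-based row/col), and the grouping metadata of the source image.
#'
#' @param labels integer label matrix from [labelComponents()].
#' @param meta named list with `source_id`, `culture_day`, `group_label`
#'   and optionally `pixel_size_um`; or an [AnnotatedImage-class] whose
#'   metadata is used.
#' @return data.frame of organoid records (zero rows if no components).
#' @export
measureOrganoids <- function(labels, meta) {
  if (is(meta, "AnnotatedImage")) meta <- metadata(meta)
  if (is.list(labels) && !is.null(labels$labels)) labels <- labels$labels
  need <- c("source_id", "culture_day", "group_label")
  missing_keys <- setdiff(need, names(meta))
  if (length(missing_keys))
    stop("missing metadata key(s) ", paste(missing_keys, collapse = ", "),
         " for ", meta$source_id %||% "<unknown source>")
  px <- meta$pixel_size_um
  if (is.null(px)) {
    warning("pixel_size_um missing for ", meta$source_id,
            "; reporting pixel areas only", call. = FALSE)
    px <- NA_real_
  }
  k <- max(labels)
  if (k == 0L)
    return(data.frame(source_id = character(), organoid_id = integer(),
                      area_pixels = integer(), area_um2 = numeric(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      culture_day = integer(), group_label = character(),
                      stringsAsFactors = FALSE))
  idx <- which(labels > 0L, arr.ind = TRUE)
  lv <- labels[labels > 0L]
  area <- as.integer(tabulate(lv, nbins = k))
  crow <- tapply(idx[, 1L], lv, mean)
  ccol <- tapply(idx[, 2L], lv, mean)
  data.frame(source_id = meta$source_id, organoid_id = seq_len(k),
             area_pixels = area, area_um2 = area * px^2,
             centroid_row = as.numeric(crow), centroid_col = as.numeric(ccol),
             culture_day = as.integer(meta$culture_day),
             group_label = meta$group_label, stringsAsFactors = FALSE)
}

#' Summarize organoid areas by treatment group and culture day
#'
#' Median and quartiles (linear-interpolation type-7 quantiles) of the
#' per-organoid areas for every (group, day) combination present in the
#' records, plus counts and total area. Summaries use physical areas when
#' available, else pixel areas.
#'
#' @param records data.frame from [measureOrganoids()] (rows concatenated
#'   over images).
#' @return data.frame with one row per (group_label, culture_day):
#'   `n_organoids`, `q1_area`, `median_area`, `q3_area`, `total_area`.
#' @export
summarizeGroups <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  area <- if (all(is.finite(records$area_um2))) records$area_um2
          else records$area_pixels
  key <- interaction(records$group_label, records$culture_day, drop = TRUE)
  out <- lapply(levels(key), function(lv) {
    a <- area[key == lv]
    q <- stats::quantile(a, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    i <- which(key == lv)[1L]
    data.frame(group_label = records$group_label[i],
               culture_day = records$culture_day[i],
               n_organoids = length(a), q1_area = q[1L], median_area = q[2L],
               q3_area = q[3L], total_area = sum(a),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$group_label, out$culture_day), , drop = FALSE]
}

#' Export long-format violin-plot data
#'
#' Writes one CSV row per organoid (`group_label`, `culture_day`,
#' `source_id`, `organoid_id`, `area_um2`) -- sufficient to redraw
#' area-distribution violins per group and day in any plotting tool.
#' Areas are written with 17 significant digits so the round trip is exact.
#'
#' @param records data.frame from [measureOrganoids()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
exportViolinData <- function(records, path) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  if (!dir.exists(dirname(path))) stop("cannot write to ", path,
                                       ": directory does not exist")
  df <- records[, c("group_label", "culture_day", "source_id", "organoid_id",
                    "area_um2")]
  df$area_um2 <- vapply(df$area_um2, function(x) sprintf("%.17g", x), character(1))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Simulate a drug-screening experiment
#'
#' The synthetic drug-effect fixture: three treatment groups (untreated
#' CTR and two drugs, RA and B0107) imaged on culture days 1, 3, 5 and 7.
#' Per-organoid areas are log-normal; all groups share the same location
#' parameter on days 1-3 (initial growth, no treatment effect), while from
#' day 5 the CTR location is raised (drugs inhibit growth), with the gap
#' widening at day 7. Scenes are rendered with non-overlapping organoids so
#' each body stays one connected component.
#'
#' @param seed integer seed.
#' @param nImagesPerGroup scenes per (group, day) (default 4).
#' @param nOrganoids organoids per scene (default 8).
#' @param imageSize scene side in pixels (default 256).
#' @param days culture days imaged (default `c(1, 3, 5, 7)`).
#' @param baselineLogArea log pixel-area location on day 1 (default
#'   `log(150)`).
#' @param growthPerDay shared log-area growth per day (default 0.18).
#' @param ctrBoost named extra CTR log-area at days 5 and 7 (default
#'   `c("5" = 0.6, "7" = 0.9)`).
#' @param sigmaLog log-area spread (default 0.35).
#' @return List with `images` (list of [AnnotatedImage-class]) and
#'   `params` (the simulation settings).
#' @export
simulateDrugScreen <- function(seed = 1L, nImagesPerGroup = 4L, nOrganoids = 8L,
                               imageSize = 256L, days = c(1L, 3L, 5L, 7L),
                               baselineLogArea = log(150), growthPerDay = 0.18,
                               ctrBoost = c("5" = 0.6, "7" = 0.9),
                               sigmaLog = 0.35) {
  groups <- c("CTR", "RA", "B0107")
  setGlobalSeed(seed)
  images <- list()
  for (day in days) {
    for (g in groups) {
      mu <- baselineLogArea + growthPerDay * (day - 1)
      if (g == "CTR" && as.character(day) %in% names(ctrBoost))
        mu <- mu + ctrBoost[[as.character(day)]]
      for (i in seq_len(nImagesPerGroup)) {
        sd_seed <- sample.int(2^30, 1L)
        sampler <- local({
          mu0 <- mu
          function(n) {
            a <- stats::rlnorm(n, mu0, sigmaLog)
            pmin(pmax(sqrt(a / pi), 4), imageSize / 6)
          }
        })
        sp <- sceneSpec(width = imageSize, height = imageSize,
                        nOrganoids = nOrganoids,
                        radiusRange = c(4, imageSize / 6),
                        overlapAllowed = FALSE, noiseSigma = 6,
                        illuminationAmplitude = 0.15, seed = sd_seed)
        sp$radiusSampler <- sampler
        images[[length(images) + 1L]] <- generateSyntheticScene(
          sp, source_id = sprintf("%s_d%d_%02d", g, day, i),
          culture_day = day, group_label = g)
      }
    }
  }
  list(images = images,
       params = list(seed = seed, nImagesPerGroup = nImagesPerGroup,
                     nOrganoids = nOrganoids, imageSize = imageSize,
                     days = days, baselineLogArea = baselineLogArea,
                     growthPerDay = growthPerDay, ctrBoost = ctrBoost,
                     sigmaLog = sigmaLog))
}

#' Run the screening pipeline on a set of masks
#'
#' Convenience wrapper: labels components, measures organoids and
#' concatenates records over a list of annotated images (using their
#' ground-truth or predicted masks).
#'
#' @param images list of [AnnotatedImage-class].
#' @param masks optional list of predicted masks (defaults to each image's
#'   own mask).
#' @param connectivity,minSize see [labelComponents()].
#' @return data.frame of organoid records.
#' @export
screenImages <- function(images, masks = NULL, connectivity = 8L,
                         minSize = 30L) {
  recs <- lapply(seq_along(images), function(i) {
    m <- if (is.null(masks)) maskArray(images[[i]]) else masks[[i]]
    lab <- labelComponents(m, connectivity, minSize)
    measureOrganoids(lab, images[[i]])
  })
  do.call(rbind, recs)
}
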