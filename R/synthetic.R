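# ---------------------------------------------------------------------------
# Synthetic organoid scenes: bright elliptical bodies with a darker rim on a
# textured background, a smooth uneven-illumination field and additive
# Gaussian noise -- the appearance of brightfield organoid micrographs
# collected across days and imaging sessions.
# ---------------------------------------------------------------------------

#' Synthetic scene specification
#'
#' Parameters of one generated organoid scene. Organoids are ellipses with
#' randomized axes and rotation (optionally radially perturbed boundaries),
#' rendered brighter than the background with a darker rim; the image adds
#' a low-frequency background texture, a smooth multiplicative illumination
#' field of relative amplitude `illuminationAmplitude`, and Gaussian pixel
#' noise of standard deviation `noiseSigma` (8-bit intensity units).
#'
#' @param width,height scene size in pixels.
#' @param nOrganoids number of organoids (>= 0).
#' @param radiusRange `c(min, max)` semi-axis range in pixels; the maximum
#'   must stay below half the smaller scene side.
#' @param intensityContrast organoid brightness offset as a fraction of the
#'   8-bit range, in (0, 1].
#' @param noiseSigma additive Gaussian noise sd (>= 0).
#' @param illuminationAmplitude relative amplitude of the smooth
#'   illumination field, in [0, 1).
#' @param overlapAllowed may organoid footprints overlap?
#' @param boundaryJitter relative radial boundary perturbation (0 = exact
#'   ellipses).
#' @param seed integer RNG seed; scenes are bit-reproducible given the spec.
#' @return Object of class `sceneSpec`.
#' @export
sceneSpec <- function(width = 256L, height = 256L, nOrganoids = 8L,
                      radiusRange = c(8, 28), intensityContrast = 0.35,
                      noiseSigma = 8, illuminationAmplitude = 0.2,
                      overlapAllowed = TRUE, boundaryJitter = 0,
                      seed = 1L) {
  stopifnot(width >= 8, height >= 8, nOrganoids >= 0,
            length(radiusRange) == 2L, radiusRange[1L] > 0,
            radiusRange[1L] <= radiusRange[2L],
            radiusRange[2L] < min(width, height) / 2,
            intensityContrast > 0, intensityContrast <= 1,
            noiseSigma >= 0,
            illuminationAmplitude >= 0, illuminationAmplitude < 1,
            boundaryJitter >= 0, boundaryJitter < 0.5)
  structure(list(width = as.integer(width), height = as.integer(height),
                 nOrganoids = as.integer(nOrganoids),
                 radiusRange = as.numeric(radiusRange),
                 intensityContrast = intensityContrast,
                 noiseSigma = noiseSigma,
                 illuminationAmplitude = illuminationAmplitude,
                 overlapAllowed = isTRUE(overlapAllowed),
                 boundaryJitter = boundaryJitter,
                 seed = as.integer(seed)),
            class = "sceneSpec")
}

# Smooth random field in [-1, 1]: coarse Gaussian grid, bilinear upsampling.
smoothField <- function(h, w, grid = 4L) {
  g <- matrix(stats::rnorm(grid * grid), grid, grid)
  f <- cpp_resize_bilinear(array(g, c(grid, grid, 1L)), h, w)[, , 1L]
  mx <- max(abs(f))
  if (mx > 0) f / mx else f
}

#' Generate a synthetic organoid scene
#'
#' Renders the scene described by a [sceneSpec()] and returns it with its
#' exact ground-truth mask (the union of the rendered organoid footprints).
#' Deterministic for a fixed spec: the spec's seed initializes the RNG.
#'
#' @param spec a [sceneSpec()].
#' @param source_id,culture_day,group_label,pixel_size_um metadata for the
#'   resulting [AnnotatedImage-class].
#' @return An [AnnotatedImage-class].
#' @export
generateSyntheticScene <- function(spec, source_id = paste0("scene", spec$seed),
                                   culture_day = 1L, group_label = "CTR",
                                   pixel_size_um = 1.0) {
  stopifnot(inherits(spec, "sceneSpec"))
  h <- spec$height; w <- spec$width
  withr_seed <- spec$seed
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(withr_seed)

  base <- 105 + 10 * smoothField(h, w, 5L)   # textured background
  mask <- matrix(0L, h, w)
  gray <- base

  # sample organoid geometry (rejection sampling when overlap is forbidden)
  placed <- list()
  tries <- 0L
  while (length(placed) < spec$nOrganoids && tries < 200L * max(1L, spec$nOrganoids)) {
    tries <- tries + 1L
    if (!is.null(spec$radiusSampler)) {
      # custom radius distribution (e.g. log-normal areas in the screening
      # fixture); mild random eccentricity around the sampled radius
      r0 <- min(max(spec$radiusSampler(1L), spec$radiusRange[1L]),
                spec$radiusRange[2L])
      f <- exp(stats::runif(1, -0.08, 0.08))
      a <- r0 * f
      b <- r0 / f
    } else {
      a <- stats::runif(1, spec$radiusRange[1L], spec$radiusRange[2L])
      b <- stats::runif(1, spec$radiusRange[1L], spec$radiusRange[2L])
    }
    r <- max(a, b)
    cy <- stats::runif(1, r, h - 1 - r)
    cx <- stats::runif(1, r, w - 1 - r)
    if (!spec$overlapAllowed && length(placed)) {
      ok <- all(vapply(placed, function(p)
        sqrt((p$cy - cy)^2 + (p$cx - cx)^2) > (max(p$a, p$b) + r + 1), logical(1)))
      if (!ok) next
    }
    placed[[length(placed) + 1L]] <- list(
      cy = cy, cx = cx, a = a, b = b,
      theta = stats::runif(1, 0, pi),
      bright = stats::runif(1, 0.7, 1) * spec$intensityContrast * 255,
      jitk = sample(3:6, 1L), jitph = stats::runif(1, 0, 2 * pi))
  }
  if (spec$nOrganoids > 0L && length(placed) < spec$nOrganoids)
    warning("placed only ", length(placed), " of ", spec$nOrganoids,
            " organoids without overlap")

  for (p in placed) {
    r <- max(p$a, p$b) * (1 + spec$boundaryJitter)
    rows <- max(0L, floor(p$cy - r)):min(h - 1L, ceiling(p$cy + r))
    cols <- max(0L, floor(p$cx - r)):min(w - 1L, ceiling(p$cx + r))
    dy <- outer(rows - p$cy, rep(1, length(cols)))
    dx <- outer(rep(1, length(rows)), cols - p$cx)
    u <- (dx * cos(p$theta) + dy * sin(p$theta)) / p$a
    v <- (-dx * sin(p$theta) + dy * cos(p$theta)) / p$b
    rho <- sqrt(u^2 + v^2)
    lim <- 1
    if (spec$boundaryJitter > 0) {
      phi <- atan2(v, u)
      lim <- 1 + spec$boundaryJitter * sin(p$jitk * phi + p$jitph)
    }
    inside <- rho <= lim
    # interior brightening with a darker rim band near the boundary
    prof <- p$bright * (0.75 + 0.25 * pmax(0, 1 - rho^2))
    rim <- rho > 0.82 * lim & inside
    delta <- ifelse(inside, prof, 0) - ifelse(rim, 1.4 * p$bright * 0.5, 0)
    gray[rows + 1L, cols + 1L] <- gray[rows + 1L, cols + 1L] + delta
    mask[rows + 1L, cols + 1L][inside] <- 1L
  }

  illum <- 1 + spec$illuminationAmplitude * smoothField(h, w, 3L)
  gray <- gray * illum
  img <- array(0, c(h, w, 3L))
  chan_gain <- c(1, 0.98, 0.95)  # faint warm cast typical of brightfield
  for (ch in 1:3) {
    v <- gray * chan_gain[ch]
    if (spec$noiseSigma > 0) v <- v + stats::rnorm(h * w, 0, spec$noiseSigma)
    img[, , ch] <- v
  }
  img <- round(pmin(pmax(img, 0), 255))
  AnnotatedImage(img, mask, source_id = source_id, culture_day = culture_day,
                 group_label = group_label, pixel_size_um = pixel_size_um)
}
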