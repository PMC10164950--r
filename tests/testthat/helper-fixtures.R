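# Shared fixtures and independent oracles for the test suite.

# Small network configurations so unit tests stay fast; channel counts are
# scaled-down but the topology (stage count, levels, skips) is unchanged.
microConfig <- function(...) {
  networkConfig(backbone = backboneConfig(widthScale = 1 / 16), ...)
}
tinyConfig <- function(...) {
  networkConfig(backbone = backboneConfig(widthScale = 1 / 8), ...)
}

makeTiles <- function(n, size = 64L, nOrganoids = 3L, seedBase = 100L,
                      radiusRange = c(6, 14)) {
  lapply(seq_len(n), function(i) {
    sp <- sceneSpec(width = size, height = size, nOrganoids = nOrganoids,
                    radiusRange = radiusRange, noiseSigma = 6,
                    seed = seedBase + i)
    generateSyntheticScene(sp, source_id = paste0("tile", i))
  })
}

# Independent point-in-polygon oracle: even-odd ray casting with explicit
# on-edge detection (boundary counts as inside).
oraclePointInPolygon <- function(px, py, xv, yv) {
  n <- length(xv)
  onEdge <- FALSE
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- xv[i]; yi <- yv[i]; xj <- xv[j]; yj <- yv[j]
    # on-segment test
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    if (abs(cross) < 1e-9 &&
        px >= min(xi, xj) - 1e-9 && px <= max(xi, xj) + 1e-9 &&
        py >= min(yi, yj) - 1e-9 && py <= max(yi, yj) + 1e-9)
      onEdge <- TRUE
    if ((yi > py) != (yj > py)) {
      xint <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside || onEdge
}

oracleRasterize <- function(ann) {
  h <- ann$imageHeight; w <- ann$imageWidth
  mask <- matrix(0L, h, w)
  for (s in ann$shapes) {
    for (r in 0:(h - 1L)) for (cc in 0:(w - 1L)) {
      if (oraclePointInPolygon(cc, r, s$points[, 1L], s$points[, 2L]))
        mask[r + 1L, cc + 1L] <- 1L
    }
  }
  mask
}

# Independent flood-fill component labeling oracle (recursive queue in R).
oracleLabel <- function(mask, connectivity = 8L, minSize = 1L) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  if (connectivity == 8L) {
    dr <- c(-1, 1, 0, 0, -1, -1, 1, 1); dc <- c(0, 0, -1, 1, -1, 1, -1, 1)
  } else {
    dr <- c(-1, 1, 0, 0); dc <- c(0, 0, -1, 1)
  }
  nxt <- 0L
  for (c0 in seq_len(w)) for (r0 in seq_len(h)) {
    if (mask[r0, c0] == 0L || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0)); lab[r0, c0] <- nxt
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (t in seq_along(dr)) {
        nr <- p[1L] + dr[t]; nc <- p[2L] + dc[t]
        if (nr >= 1 && nr <= h && nc >= 1 && nc <= w &&
            mask[nr, nc] == 1L && lab[nr, nc] == 0L) {
          lab[nr, nc] <- nxt
          queue[[length(queue) + 1L]] <- c(nr, nc)
        }
      }
    }
  }
  # min-size filter + compact renumber, first-encounter order
  if (nxt > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = nxt)
    remap <- integer(nxt); keep <- 0L
    for (k in seq_len(nxt)) if (sizes[k] >= minSize) { keep <- keep + 1L; remap[k] <- keep }
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

# Map of component pixel-sets irrespective of label numbering.
componentSignature <- function(lab) {
  ks <- setdiff(sort(unique(as.vector(lab))), 0L)
  sort(vapply(ks, function(k) paste(which(lab == k), collapse = ","), character(1)))
}

randomBinaryMask <- function(h, w, p = 0.4) {
  matrix(as.integer(stats::runif(h * w) < p), h, w)
}
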