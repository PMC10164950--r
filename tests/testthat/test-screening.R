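test_that("two disjoint squares are two components; min-size filters them", {
  m <- matrix(0L, 10, 10)
  m[2:3, 2:3] <- 1L
  m[7:8, 7:8] <- 1L
  lab <- labelComponents(m, connectivity = 8, minSize = 1)
  expect_identical(lab$count, 2L)
  areas <- tabulate(lab$labels[lab$labels > 0])
  expect_identical(sort(areas), c(4L, 4L))
  expect_identical(labelComponents(m, minSize = 5)$count, 0L)
  expect_error(labelComponents(matrix(2L, 2, 2)), "binary")
  expect_error(labelComponents(m, connectivity = 6), "4 or 8")
})

test_that("diagonal touch merges under 8- but not 4-connectivity", {
  m <- matrix(0L, 4, 4)
  m[1, 1] <- 1L; m[2, 2] <- 1L
  expect_identical(labelComponents(m, 8, 1)$count, 1L)
  expect_identical(labelComponents(m, 4, 1)$count, 2L)
})

test_that("component labeling agrees with a flood-fill oracle", {
  set.seed(41)
  for (rep in 1:15) {
    m <- randomBinaryMask(24, 24, p = runif(1, 0.3, 0.6))
    for (conn in c(4L, 8L)) {
      lab <- labelComponents(m, conn, minSize = 1)$labels
      orc <- oracleLabel(m, conn, minSize = 1)
      expect_identical(componentSignature(lab), componentSignature(orc),
                       info = paste("rep", rep, "conn", conn))
    }
    # with the min-size filter as well
    lab <- labelComponents(m, 8L, minSize = 4)$labels
    orc <- oracleLabel(m, 8L, minSize = 4)
    expect_identical(componentSignature(lab), componentSignature(orc))
  }
})

test_that("a solid square measures its exact area and centroid", {
  m <- matrix(0L, 9, 9); m[4:6, 4:6] <- 1L
  lab <- labelComponents(m, minSize = 1)
  rec <- measureOrganoids(lab, list(source_id = "sq", culture_day = 2,
                                    group_label = "CTR", pixel_size_um = 1))
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$area_pixels, 9L)
  expect_equal(rec$centroid_row, 5)
  expect_equal(rec$centroid_col, 5)
  expect_identical(rec$culture_day, 2L)
})

test_that("physical areas scale with the squared pixel size", {
  m <- matrix(0L, 6, 6); m[2:4, 2:4] <- 1L
  lab <- labelComponents(m, minSize = 1)
  rec <- measureOrganoids(lab, list(source_id = "s", culture_day = 1,
                                    group_label = "CTR", pixel_size_um = 2))
  expect_equal(rec$area_um2, 4 * rec$area_pixels)
  expect_warning(
    rec2 <- measureOrganoids(lab, list(source_id = "s", culture_day = 1,
                                       group_label = "CTR")),
    "pixel_size_um")
  expect_true(is.na(rec2$area_um2))
  expect_error(measureOrganoids(lab, list(source_id = "s")), "culture_day")
})

test_that("per-label areas sum to the filtered foreground pixel count", {
  set.seed(42)
  m <- randomBinaryMask(32, 32, 0.45)
  lab <- labelComponents(m, 8L, minSize = 5)
  rec <- measureOrganoids(lab, list(source_id = "x", culture_day = 1,
                                    group_label = "CTR", pixel_size_um = 1))
  expect_identical(sum(rec$area_pixels), sum(lab$labels > 0L))
})

test_that("group summaries use type-7 quantiles and are order-invariant", {
  rec <- data.frame(source_id = "s", organoid_id = 1:4,
                    area_pixels = c(1L, 2L, 3L, 4L),
                    area_um2 = c(1, 2, 3, 4),
                    centroid_row = 0, centroid_col = 0,
                    culture_day = 1L, group_label = "CTR")
  s <- summarizeGroups(rec)
  expect_equal(s$q1_area, 1.75)
  expect_equal(s$median_area, 2.5)
  expect_equal(s$q3_area, 3.25)
  s3 <- summarizeGroups(rec[1:3, ])
  expect_equal(s3$median_area, 2)
  perm <- summarizeGroups(rec[sample(4), ])
  expect_equal(perm, s)
})

test_that("violin export writes one row per organoid and round trips", {
  set.seed(43)
  rec <- data.frame(source_id = rep(c("a", "b"), each = 3), organoid_id = 1:6,
                    area_pixels = 10:15,
                    area_um2 = (10:15) * pi + 1e-7 * runif(6),
                    centroid_row = 0, centroid_col = 0,
                    culture_day = rep(c(1L, 5L), each = 3),
                    group_label = rep(c("CTR", "RA"), each = 3))
  tmp <- tempfile(fileext = ".csv")
  exportViolinData(rec, tmp)
  back <- utils::read.csv(tmp)
  expect_identical(nrow(back), 6L)
  expect_equal(back$area_um2, rec$area_um2, tolerance = 0)
  # an independent aggregation of the CSV reproduces the summaries
  med <- tapply(back$area_um2, interaction(back$group_label, back$culture_day,
                                           drop = TRUE), median)
  s <- summarizeGroups(rec)
  expect_equal(as.numeric(med[paste(s$group_label, s$culture_day, sep = ".")]),
               s$median_area)
  expect_error(exportViolinData(rec, file.path(tempdir(), "nope", "x.csv")),
               "directory")
})

test_that("the screening pipeline recovers the simulated drug effect", {
  sim <- simulateDrugScreen(seed = 7, nImagesPerGroup = 3, nOrganoids = 6,
                            imageSize = 192)
  rec <- screenImages(sim$images, minSize = 30)
  s <- summarizeGroups(rec)
  med <- function(g, d) s$median_area[s$group_label == g & s$culture_day == d]
  for (d in c(5L, 7L)) {
    expect_gt(med("CTR", d), med("RA", d))
    expect_gt(med("CTR", d), med("B0107", d))
  }
  # early days: no group separation beyond sampling noise
  for (d in c(1L, 3L)) {
    ms <- c(med("CTR", d), med("RA", d), med("B0107", d))
    expect_lt(max(ms) / min(ms), 1.6)
  }
})
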