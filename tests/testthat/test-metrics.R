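## run mask -> skeleton -> graph -> objects in one step
measureMask <- function(m, psz = 1) {
  mask <- mkMask(m, psz)
  g <- buildSkeletonGraph(tagAndLabel(skeletonize(mask)))
  list(mask = mask, graph = g, objects = measureObjects(mask, g))
}

test_that("a thick plus cross is one network with four branches", {
  m <- matrix(FALSE, 41, 41)
  m[20:22, 6:36] <- TRUE; m[6:36, 20:22] <- TRUE
  res <- measureMask(m)
  obj <- res$objects
  expect_identical(nrow(obj), 1L)
  expect_true(obj$is_network)
  expect_identical(obj$junction_count, 1L)
  expect_identical(obj$branch_count, 4L)
  expect_equal(obj$area_um2, sum(m))
})

test_that("two disjoint bars are two non-network objects", {
  m <- matrix(FALSE, 30, 30)
  m[5:7, 4:14] <- TRUE; m[20:22, 4:14] <- TRUE
  obj <- measureMask(m)$objects
  expect_identical(nrow(obj), 2L)
  expect_false(any(obj$is_network))
  expect_identical(obj$branch_count, c(1L, 1L))
  expect_equal(obj$area_um2, c(33, 33))
})

test_that("per-object junction counts match generator ground truth", {
  p <- simParams(nObjects = 6L, branchingProb = 0.6, seed = 8L,
                 gaussianNoiseSd = 0, poissonGain = 0, psfSigmaPx = 0)
  s <- simulateImage(p)
  res <- measureMask(pixels(s$truthMask), psz = 0.1)
  tj <- s$truth$junctions
  nd <- graphNodes(res$graph)
  ## every truth junction has exactly one recovered junction node nearby
  for (i in seq_len(nrow(tj))) {
    jn <- nd[nd$type == "junction", ]
    d <- sqrt((jn$row - tj$row[i])^2 + (jn$col - tj$col[i])^2)
    expect_identical(sum(d < 4), 1L)
  }
  expect_identical(sum(res$objects$junction_count),
                   s$truth$trueJunctionCount)
})

test_that("summarizeCell computes the documented attribute row", {
  m <- matrix(FALSE, 100, 100); m[41:50, 41:50] <- TRUE
  res <- measureMask(m, psz = 1)
  row <- summarizeCell("cell1", res$mask, res$objects, "img1",
                       paramsFingerprint = "abc")
  expect_equal(row$cell_area_um2, 10000)
  expect_equal(row$mito_coverage_pct, 1.0)
  expect_identical(row$object_count, 1L)
  expect_equal(row$objects_per_100um2, 0.01)
  expect_identical(row$roi_id, "cell1")
  expect_identical(row$params_fingerprint, "abc")
})

test_that("an empty mask reports zero coverage and missing means", {
  mask <- mkMask(matrix(FALSE, 50, 50))
  row <- summarizeCell("empty", mask,
                       measureObjects(mask, buildSkeletonGraph(
                         tagAndLabel(skeletonize(mask)))))
  expect_equal(row$mito_coverage_pct, 0)
  expect_identical(row$object_count, 0L)
  expect_true(is.na(row$mean_object_length_um))
  expect_true(is.na(row$mean_object_area_um2))
  expect_true(is.na(row$mean_junctions_per_network))
  expect_identical(row$network_count, 0L)
})

test_that("polygon validity masks restrict the cell area used for coverage", {
  m <- matrix(FALSE, 40, 40); m[10:19, 10:19] <- TRUE
  vm <- matrix(FALSE, 40, 40); vm[1:20, 1:40] <- TRUE   # top half valid
  mask <- new("BinaryMask", pixels = m, pixelSizeUm = 1, validMask = vm)
  g <- buildSkeletonGraph(tagAndLabel(skeletonize(mask)))
  row <- summarizeCell("poly", mask, measureObjects(mask, g))
  expect_equal(row$cell_area_um2, 800)
  expect_equal(row$mito_coverage_pct, 100 * 100 / 800)
})

test_that("metrics obey the pixel-size scaling laws", {
  p <- simParams(seed = 12L, gaussianNoiseSd = 0, poissonGain = 0)
  s <- simulateImage(p)
  px <- pixels(s$image)
  rows <- lapply(c(0.1, 0.2), function(psz)
    quantifyOne(grayImage(px, pixelSizeUm = psz, sourceId = "s"),
                runConfig(pixelSizeUm = psz)))
  a <- rows[[1]]; b <- rows[[2]]
  expect_equal(b$mean_object_length_um, 2 * a$mean_object_length_um)
  expect_equal(b$mean_object_area_um2, 4 * a$mean_object_area_um2)
  expect_equal(b$cell_area_um2, 4 * a$cell_area_um2)
  expect_equal(b$objects_per_100um2, a$objects_per_100um2 / 4)
  expect_identical(b$object_count, a$object_count)
  expect_identical(b$junction_count_total, a$junction_count_total)
  expect_identical(b$network_count, a$network_count)
  expect_equal(b$mito_coverage_pct, a$mito_coverage_pct)
})

test_that("metrics are additive over a cut that no object crosses", {
  set.seed(31)
  m <- matrix(FALSE, 60, 121)
  m[10:12, 5:50] <- TRUE          # object left of the cut (col <= 60)
  m[30:40, 20:22] <- TRUE
  m[50:52, 70:115] <- TRUE        # object right of the cut
  m[5:7, 80:100] <- TRUE
  whole <- measureMask(m)
  left <- measureMask(m[, 1:60])
  right <- measureMask(m[, 61:121])
  expect_identical(nrow(whole$objects),
                   nrow(left$objects) + nrow(right$objects))
  expect_equal(sum(whole$objects$area_um2),
               sum(left$objects$area_um2) + sum(right$objects$area_um2))
  expect_equal(sum(whole$objects$skeleton_length_um),
               sum(left$objects$skeleton_length_um) +
                 sum(right$objects$skeleton_length_um))
})

test_that("longest-branch length mode reports the maximal branch", {
  m <- plusCrossMask()
  mask <- mkMask(m)
  g <- buildSkeletonGraph(tagAndLabel(mask))
  obj <- measureObjects(mask, g)
  expect_equal(obj$longest_branch_um, 10)
  expect_equal(obj$skeleton_length_um, 40)
  rowT <- summarizeCell("x", mask, obj, lengthMode = "total")
  rowL <- summarizeCell("x", mask, obj, lengthMode = "longest-branch")
  expect_equal(rowT$mean_object_length_um, 40)
  expect_equal(rowL$mean_object_length_um, 10)
})

test_that("metrics CSV round-trips with fixed columns and empty-field missing values", {
  d <- withr::local_tempdir()
  m <- matrix(FALSE, 40, 40); m[10:12, 5:30] <- TRUE
  res <- measureMask(m)
  row1 <- summarizeCell("a", res$mask, res$objects, "img",
                        paramsFingerprint = "ff")
  empty <- mkMask(matrix(FALSE, 30, 30))
  row0 <- summarizeCell("b", empty,
                        measureObjects(empty, buildSkeletonGraph(
                          tagAndLabel(skeletonize(empty)))), "img",
                        paramsFingerprint = "ff")
  rows <- rbind(row1, row0, row1)
  p <- file.path(d, "m.csv")
  writeMetricsCsv(rows, p)
  lines <- readLines(p)
  expect_length(lines, 4)
  expect_identical(strsplit(lines[1], ",")[[1]],
                   paste0("\"", MitoNetQuant:::metricsColumns, "\""))
  back <- readMetricsCsv(p)
  expect_equal(back$mito_coverage_pct, signif(rows$mito_coverage_pct, 6))
  expect_true(is.na(back$mean_object_length_um[2]))
  expect_match(lines[3], ",,")   # missing means are empty fields, not 0

  writeMetricsCsv(rows[0, ], file.path(d, "e.csv"))
  expect_length(readLines(file.path(d, "e.csv")), 1)

  mixed <- rbind(row1, transform(row0, params_fingerprint = "other"))
  expect_error(writeMetricsCsv(mixed, file.path(d, "x.csv")), "mixed")
  expect_silent(writeMetricsCsv(mixed, file.path(d, "x.csv"),
                                allowMixed = TRUE))
})
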