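## write a few synthetic single-cell frames to a directory
writeSimFrames <- function(dir, seeds, nObjects = 10L) {
  dir.create(dir, showWarnings = FALSE)
  for (sd in seeds) {
    s <- simulateImage(simParams(nObjects = nObjects, seed = sd))
    writeImageTiff(s$image, file.path(dir, sprintf("cell%02d.tif", sd)))
  }
}

test_that("quantifyOne is deterministic end to end", {
  s <- simulateImage(simParams(seed = 41L))
  cfg <- runConfig(pixelSizeUm = 0.1)
  r1 <- quantifyOne(s$image, cfg)
  r2 <- quantifyOne(s$image, cfg)
  expect_identical(r1, r2)
  expect_identical(r1$params_fingerprint, paramsFingerprint(cfg))
})

test_that("a fused-preset frame is quantified as a branched network", {
  pair <- simulateConditionPair(simParams(seed = 2L), 5L, 50L)
  row <- quantifyOne(pair$fused$image, runConfig(pixelSizeUm = 0.1))
  expect_gte(row$network_count, 1L)
  expect_gte(row$junction_count_total, 1L)
})

test_that("batch over a cropped directory writes one row per frame in name order", {
  d <- withr::local_tempdir()
  crops <- file.path(d, "crops")
  writeSimFrames(crops, seeds = 1:5)
  res <- runBatch(crops, file.path(d, "out.csv"),
                  runConfig(pixelSizeUm = 0.1))
  expect_identical(nrow(res$metrics), 5L)
  expect_identical(res$metrics$roi_id, sprintf("cell%02d", 1:5))
  expect_identical(nrow(res$failures), 0L)
  expect_length(unique(res$metrics$params_fingerprint), 1L)
  got <- readMetricsCsv(file.path(d, "out.csv"))
  expect_identical(nrow(got), 5L)
})

test_that("a corrupted frame is logged and skipped; re-runs are byte-identical", {
  d <- withr::local_tempdir()
  crops <- file.path(d, "crops")
  writeSimFrames(crops, seeds = 1:4)
  writeLines("not a tiff", file.path(crops, "cell99.tif"))
  cfg <- runConfig(pixelSizeUm = 0.1)
  suppressMessages(res <- runBatch(crops, file.path(d, "a.csv"), cfg))
  expect_identical(nrow(res$metrics), 4L)
  expect_identical(res$failures$roi_id, "cell99")
  suppressMessages(runBatch(crops, file.path(d, "b.csv"), cfg))
  expect_identical(readBin(file.path(d, "a.csv"), "raw", 1e5),
                   readBin(file.path(d, "b.csv"), "raw", 1e5))
})

test_that("manifest batches crop and quantify in manifest order", {
  d <- withr::local_tempdir()
  s <- simulateImage(simParams(imageSizePx = 320L, nObjects = 25L,
                               seed = 13L))
  src <- file.path(d, "frame.tif")
  writeImageTiff(s$image, src)
  man <- new("RoiManifest",
             entries = list(
               roi("cellB", "frame", rect = c(160, 0, 160, 160)),
               roi("cellA", "frame", rect = c(0, 0, 160, 160))),
             imagePaths = c(frame = src))
  res <- runBatch(man, file.path(d, "man.csv"),
                  runConfig(pixelSizeUm = 0.1))
  expect_identical(res$metrics$roi_id, c("cellB", "cellA"))
  expect_identical(res$metrics$source_id, c("frame", "frame"))
  ## row set is order-independent
  man2 <- new("RoiManifest", entries = rev(man@entries),
              imagePaths = man@imagePaths)
  res2 <- runBatch(man2, file.path(d, "man2.csv"),
                   runConfig(pixelSizeUm = 0.1))
  expect_identical(res$metrics[order(res$metrics$roi_id), ],
                   res2$metrics[order(res2$metrics$roi_id), ],
                   ignore_attr = TRUE)
  expect_error(runBatch(new("RoiManifest", entries = list(),
                            imagePaths = character(0)),
                        file.path(d, "x.csv")), "empty")
})

test_that("YAML configs resolve into fingerprinted run configurations", {
  d <- withr::local_tempdir()
  p <- file.path(d, "cfg.yaml")
  writeLines(c("claheTiles: 4", "unsharpAmount: 0.3",
               "pixelSizeUm: 0.065", "lengthMode: longest-branch",
               "pruneSpursPx: 0"), p)
  cfg <- readRunConfig(p)
  expect_identical(cfg@preprocess@claheTiles, 4L)
  expect_equal(cfg@preprocess@unsharpAmount, 0.3)
  expect_identical(cfg@lengthMode, "longest-branch")
  expect_equal(cfg@pruneSpursPx, 0)
  expect_false(paramsFingerprint(cfg) == paramsFingerprint(runConfig()))
  ## same settings -> same fingerprint
  expect_identical(paramsFingerprint(readRunConfig(p)),
                   paramsFingerprint(cfg))
})

test_that("debug overlays are written for visual inspection", {
  d <- withr::local_tempdir()
  s <- simulateImage(simParams(seed = 3L))
  st <- quantifyOne(s$image, runConfig(pixelSizeUm = 0.1),
                    returnStages = TRUE)
  pT <- writeTaggedSkeletonTiff(st$tagged, file.path(d, "tags.tif"))
  pP <- writeOverlayPng(st$mask, st$skeleton, file.path(d, "ov.png"))
  expect_true(file.exists(pT))
  expect_true(file.exists(pP))
  tags <- round(tiff::readTIFF(pT) * 255)
  expect_setequal(unique(as.vector(tags)),
                  sort(unique(as.vector(skeletonTags(st$tagged)))))
})
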