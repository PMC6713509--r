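#' @include AllClasses.R preprocess.R metrics.R
NULL

#' Construct a run configuration
#'
#' @param preprocess a [PreprocessParams-class].
#' @param lengthMode `"total"` or `"longest-branch"`.
#' @param pixelSizeUm calibration applied to images read from disk.
#' @param pruneSpursPx prune terminal skeleton spurs shorter than this many
#'   pixels (0 disables; see [pruneSpurs()]).
#' @param allowMixed permit mixed fingerprints in one CSV.
#' @return a [RunConfig-class]
#' @export
runConfig <- function(preprocess = preprocessParams(),
                      lengthMode = c("total", "longest-branch"),
                      pixelSizeUm = 1, pruneSpursPx = 3, allowMixed = FALSE) {
  new("RunConfig", preprocess = preprocess, lengthMode = match.arg(lengthMode),
      pixelSizeUm = pixelSizeUm, pruneSpursPx = pruneSpursPx,
      allowMixed = allowMixed)
}

#' Read a run configuration from a YAML file
#'
#' Recognized keys mirror [preprocessParams()] plus `lengthMode`,
#' `pixelSizeUm` and `allowMixed`; absent keys keep their defaults.
#'
#' @param path YAML file.
#' @return a [RunConfig-class]
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  ppArgs <- y[intersect(names(y), names(formals(preprocessParams)))]
  cfArgs <- y[intersect(names(y), c("lengthMode", "pixelSizeUm",
                                    "pruneSpursPx", "allowMixed"))]
  do.call(runConfig, c(list(preprocess = do.call(preprocessParams, ppArgs)),
                       cfArgs))
}

#' Fingerprint of the full parameter set
#'
#' A deterministic 8-hex-digit hash of every analysis parameter; recorded
#' in every output row so that a batch is verifiably processed with
#' constant parameters.
#'
#' @param config a [RunConfig-class]
#' @return character scalar.
#' @export
paramsFingerprint <- function(config) {
  p <- config@preprocess
  s <- paste(p@claheTiles, p@claheClip, p@medianRadiusPx, p@unsharpRadiusPx,
             p@unsharpAmount, p@thresholdMethod, p@fixedThreshold,
             p@minObjectPx, config@lengthMode, config@pixelSizeUm,
             config@pruneSpursPx, sep = "|")
  fnv1a32(s)
}

#' Quantify one cell image end to end
#'
#' Runs crop (if an ROI is given) -> enhance -> binarize -> skeletonize ->
#' tag/label -> graph -> measure -> summarize. A pure function of the pixel
#' data and the configuration; identical inputs yield identical rows.
#'
#' @param image a [GrayImage-class] (a whole frame, or an already-cropped
#'   cell when `roi` is NULL).
#' @param config a [RunConfig-class].
#' @param roi optional [RegionOfInterest-class] to crop first.
#' @param returnStages also return the intermediate mask, skeleton and
#'   graph (for debugging/overlays).
#' @return the one-row metrics data.frame, or with `returnStages` a list
#'   `(metrics, mask, skeleton, tagged, graph)`.
#' @export
quantifyOne <- function(image, config = runConfig(), roi = NULL,
                        returnStages = FALSE) {
  if (!is.null(roi)) image <- cropRoi(image, roi)
  enhanced <- enhanceImage(image, config@preprocess)
  mask <- binarizeImage(enhanced, config@preprocess)
  skel <- skeletonize(mask)
  tagged <- tagAndLabel(skel)
  if (config@pruneSpursPx > 0)
    tagged <- pruneSpurs(tagged, config@pruneSpursPx)
  graph <- buildSkeletonGraph(tagged)
  objects <- measureObjects(mask, graph)
  row <- summarizeCell(
    roiIdStr = if (!is.null(roi)) roi@roiId else image@sourceId,
    mask = mask, objects = objects,
    sourceIdStr = if (!is.null(roi)) roi@sourceId else image@sourceId,
    lengthMode = config@lengthMode,
    paramsFingerprint = paramsFingerprint(config))
  if (returnStages)
    list(metrics = row, mask = mask, skeleton = skel, tagged = tagged,
         graph = graph, objects = objects)
  else row
}

#' Batch quantification over a manifest or a directory of cropped cells
#'
#' Processes every ROI with constant parameters and writes one metrics CSV.
#' Per-ROI failures are logged and skipped; the run continues and the
#' failure count is reported. Output row order follows the manifest (or
#' sorted file names for a cropped directory), so re-running an identical
#' batch reproduces a byte-identical CSV.
#'
#' @param input a [RoiManifest-class], a manifest JSON path, or a directory
#'   of cropped single-cell TIFFs.
#' @param csvPath output CSV path.
#' @param config a [RunConfig-class].
#' @return list with `metrics` (data.frame), `failures` (data.frame of
#'   roi_id, message), `csvPath`.
#' @export
runBatch <- function(input, csvPath, config = runConfig()) {
  jobs <- list()   # each: list(roiId, run = function() row)
  if (is(input, "RoiManifest") ||
      (is.character(input) && file.exists(input) && !dir.exists(input))) {
    manifest <- if (is(input, "RoiManifest")) input else readRoiManifest(input)
    cache <- new.env(parent = emptyenv())
    jobs <- lapply(manifest@entries, function(r) {
      list(roiId = r@roiId, run = function() {
        key <- r@sourceId
        if (is.null(cache[[key]]))
          cache[[key]] <- readImageTiff(manifest@imagePaths[[key]],
                                        pixelSizeUm = config@pixelSizeUm)
        quantifyOne(cache[[key]], config, roi = r)
      })
    })
  } else if (is.character(input) && dir.exists(input)) {
    files <- sort(list.files(input, pattern = "\\.tiff?$", full.names = TRUE))
    jobs <- lapply(files, function(f) {
      id <- tools::file_path_sans_ext(basename(f))
      list(roiId = id, run = function() {
        img <- readImageTiff(f, pixelSizeUm = config@pixelSizeUm)
        img@sourceId <- id
        quantifyOne(img, config)
      })
    })
  } else {
    stop("input must be a RoiManifest, a manifest JSON path, ",
         "or a directory of cropped TIFFs")
  }
  if (!length(jobs)) stop("empty input set: nothing to quantify")

  rows <- list(); fails <- list()
  for (j in jobs) {
    res <- tryCatch(j$run(), error = function(e) e)
    if (inherits(res, "error")) {
      message("runBatch: ROI '", j$roiId, "' failed: ", conditionMessage(res))
      fails[[length(fails) + 1L]] <- data.frame(roi_id = j$roiId,
                                                message = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  metrics <- if (length(rows)) do.call(rbind, rows)
             else stats::setNames(
               as.data.frame(matrix(nrow = 0, ncol = length(metricsColumns))),
               metricsColumns)
  writeMetricsCsv(metrics, csvPath, allowMixed = config@allowMixed)
  failures <- if (length(fails)) do.call(rbind, fails)
              else data.frame(roi_id = character(0), message = character(0))
  list(metrics = metrics, failures = failures, csvPath = csvPath)
}

#' Write a tagged-skeleton debug TIFF
#'
#' Palette raster: 0 background, 1 slab, 2 endpoint, 3 junction.
#'
#' @param tagged a [TaggedSkeleton-class]
#' @param path output TIFF path.
#' @return the path, invisibly.
#' @export
writeTaggedSkeletonTiff <- function(tagged, path) {
  tiff::writeTIFF(tagged@tags / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write a skeleton-on-mask overlay PNG
#'
#' The binary mask in gray with the skeleton overlaid in red, the standard
#' visual check that the backbone traces the tubules.
#'
#' @param mask a [BinaryMask-class]
#' @param skeleton the skeleton [BinaryMask-class]
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
writeOverlayPng <- function(mask, skeleton, path) {
  nr <- nrow(mask@pixels); nc <- ncol(mask@pixels)
  rgb <- array(0, c(nr, nc, 3L))
  g <- matrix(0.55 * mask@pixels, nr, nc)
  rgb[, , 1L] <- g; rgb[, , 2L] <- g; rgb[, , 3L] <- g
  sk <- skeleton@pixels
  r1 <- rgb[, , 1L]; r1[sk] <- 1; rgb[, , 1L] <- r1
  g1 <- rgb[, , 2L]; g1[sk] <- 0; rgb[, , 2L] <- g1
  b1 <- rgb[, , 3L]; b1[sk] <- 0; rgb[, , 3L] <- b1
  png::writePNG(rgb, path)
  invisible(path)
}
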