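#' @import methods
NULL

## Tag codes used throughout: 0 background, 1 slab, 2 endpoint, 3 junction.
TAG_BG <- 0L; TAG_SLAB <- 1L; TAG_END <- 2L; TAG_JUNC <- 3L

#' Calibrated grayscale image
#'
#' A single-channel 2D intensity raster with its bit depth, pixel-size
#' calibration and provenance. All pipeline stages consume and produce
#' this container. An optional validity mask marks pixels that belong to
#' the cell when the image is a polygon crop.
#'
#' @slot pixels numeric matrix of non-negative intensities (row-major view:
#'   row 1 is the top image row).
#' @slot bitDepth integer, 8 or 16; intensities lie in `[0, 2^bitDepth - 1]`.
#' @slot pixelSizeUm positive scalar, microns per pixel edge (square pixels).
#' @slot sourceId provenance string (file name or ROI id).
#' @slot validMask logical matrix of the same shape (TRUE = pixel belongs to
#'   the ROI), or a 0x0 matrix when every pixel is valid.
#' @exportClass GrayImage
setClass("GrayImage",
  representation(pixels = "matrix", bitDepth = "integer",
                 pixelSizeUm = "numeric", sourceId = "character",
                 validMask = "matrix"),
  prototype(bitDepth = 8L, pixelSizeUm = 1, sourceId = "",
            validMask = matrix(logical(0), 0, 0)))

setValidity("GrayImage", function(object) {
  p <- object@pixels
  if (nrow(p) < 2L || ncol(p) < 2L)
    return("pixels must have at least 2 rows and 2 columns")
  if (!object@bitDepth %in% c(8L, 16L))
    return("bitDepth must be 8 or 16")
  if (any(p < 0) || any(p > 2^object@bitDepth - 1))
    return(sprintf("intensities must lie in [0, %d]", 2^object@bitDepth - 1))
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    return("pixelSizeUm must be a positive scalar")
  if (length(object@validMask) > 0L &&
      !identical(dim(object@validMask), dim(p)))
    return("validMask must match pixel dimensions")
  TRUE
})

#' Region of interest (one cell)
#'
#' A named rectangular or polygonal region tying a crop to its source image.
#' Rectangle coordinates follow the manifest convention: 0-based, origin at
#' the top-left, half-open `[row0, row0+height) x [col0, col0+width)`.
#' Polygon vertices are 0-based `(row, col)` pixel coordinates; the polygon
#' is rasterized with the even-odd rule, boundary pixels included.
#'
#' @slot roiId unique id within a manifest.
#' @slot sourceId id of the parent image.
#' @slot shapeType `"rectangle"` or `"polygon"`.
#' @slot rect numeric vector `(row0, col0, height, width)` (rectangle only).
#' @slot vertices n x 2 numeric matrix of `(row, col)` vertices (polygon only).
#' @exportClass RegionOfInterest
setClass("RegionOfInterest",
  representation(roiId = "character", sourceId = "character",
                 shapeType = "character", rect = "numeric",
                 vertices = "matrix"),
  prototype(rect = numeric(0), vertices = matrix(numeric(0), 0, 2)))

setValidity("RegionOfInterest", function(object) {
  if (!object@shapeType %in% c("rectangle", "polygon"))
    return("shapeType must be 'rectangle' or 'polygon'")
  if (object@shapeType == "rectangle") {
    if (length(object@rect) != 4L)
      return("rect must be (row0, col0, height, width)")
    if (object@rect[3L] < 8 || object@rect[4L] < 8)
      return("rectangle dimensions must be at least 8 x 8 px")
    if (any(object@rect[1:2] < 0))
      return("rectangle origin must be non-negative")
  } else {
    v <- object@vertices
    if (nrow(v) < 3L) return("polygon needs at least 3 vertices")
    if (any(v < 0)) return("polygon vertices must be non-negative")
    ## shoelace area: zero means all vertices are collinear
    r <- v[, 1L]; cc <- v[, 2L]
    area2 <- abs(sum(r * c(cc[-1L], cc[1L]) - cc * c(r[-1L], r[1L])))
    if (area2 == 0) return("polygon vertices are collinear")
  }
  TRUE
})

#' ROI manifest
#'
#' Ordered list of ROIs plus a map from `sourceId` to an image path,
#' the batch-cropping input.
#'
#' @slot entries list of [RegionOfInterest-class] objects.
#' @slot imagePaths named character vector, `sourceId -> path`.
#' @exportClass RoiManifest
setClass("RoiManifest",
  representation(entries = "list", imagePaths = "character"))

setValidity("RoiManifest", function(object) {
  ids <- vapply(object@entries, function(r) r@roiId, character(1))
  if (anyDuplicated(ids)) return("roiIds must be unique")
  src <- unique(vapply(object@entries, function(r) r@sourceId, character(1)))
  missing <- setdiff(src, names(object@imagePaths))
  if (length(missing))
    return(paste("unresolved sourceId(s):", paste(missing, collapse = ", ")))
  TRUE
})

#' Preprocessing parameters
#'
#' Parameters of the enhancement + binarization stage: contrast-limited
#' adaptive histogram equalization (CLAHE), median filtering, unsharp
#' masking, thresholding and speck removal. Defaults are package choices;
#' every output row records the full parameter fingerprint so batches are
#' verifiably run with constant parameters.
#'
#' @slot claheTiles integer, CLAHE grid count per axis.
#' @slot claheClip clip limit as a fraction of the tile histogram in (0, 1].
#' @slot medianRadiusPx integer median-filter radius (0 disables).
#' @slot unsharpRadiusPx Gaussian sigma of the unsharp mask (0 disables).
#' @slot unsharpAmount weight of the high-pass add-back (>= 0).
#' @slot thresholdMethod `"otsu"` or `"fixed"`.
#' @slot fixedThreshold intensity used iff `thresholdMethod == "fixed"`.
#' @slot minObjectPx connected foreground components smaller than this are
#'   removed after thresholding.
#' @exportClass PreprocessParams
setClass("PreprocessParams",
  representation(claheTiles = "integer", claheClip = "numeric",
                 medianRadiusPx = "integer", unsharpRadiusPx = "numeric",
                 unsharpAmount = "numeric", thresholdMethod = "character",
                 fixedThreshold = "numeric", minObjectPx = "integer"),
  prototype(claheTiles = 8L, claheClip = 0.01, medianRadiusPx = 1L,
            unsharpRadiusPx = 2, unsharpAmount = 0.6,
            thresholdMethod = "otsu", fixedThreshold = 0, minObjectPx = 4L))

setValidity("PreprocessParams", function(object) {
  if (object@claheTiles < 1L) return("claheTiles must be >= 1")
  if (object@claheClip <= 0 || object@claheClip > 1)
    return("claheClip must lie in (0, 1]")
  if (object@medianRadiusPx < 0L || object@unsharpRadiusPx < 0)
    return("radii must be >= 0")
  if (object@unsharpAmount < 0) return("unsharpAmount must be >= 0")
  if (!object@thresholdMethod %in% c("otsu", "fixed"))
    return("thresholdMethod must be 'otsu' or 'fixed'")
  if (object@minObjectPx < 0L) return("minObjectPx must be >= 0")
  TRUE
})

#' Binary mitochondrial mask
#'
#' Thresholded foreground of an enhanced image, with inherited calibration
#' and the threshold that produced it.
#'
#' @slot pixels logical matrix, TRUE = mitochondrial signal.
#' @slot pixelSizeUm microns per pixel edge.
#' @slot threshold the intensity threshold applied (NA for a mask not
#'   produced by thresholding, e.g. a synthetic truth render).
#' @slot validMask logical matrix of ROI-validity (0x0 when all valid).
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(pixels = "matrix", pixelSizeUm = "numeric",
                 threshold = "numeric",
                 validMask = "matrix"),
  prototype(pixelSizeUm = 1, threshold = NA_real_,
            validMask = matrix(logical(0), 0, 0)))

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@pixels)) return("pixels must be logical")
  if (object@pixelSizeUm <= 0) return("pixelSizeUm must be positive")
  if (length(object@validMask) > 0L &&
      !identical(dim(object@validMask), dim(object@pixels)))
    return("validMask must match pixel dimensions")
  TRUE
})

#' Tagged and labelled skeleton
#'
#' Per-pixel role map of a 1-px skeleton (slab / endpoint / junction,
#' assigned by 8-neighbour count) together with per-object labels from
#' 8-connected component analysis.
#'
#' @slot tags integer matrix: 0 background, 1 slab, 2 endpoint, 3 junction.
#' @slot labels integer matrix of object ids, 0 = background; labels are
#'   1..K in raster-scan order of each object's first pixel.
#' @slot pixelSizeUm microns per pixel edge.
#' @exportClass TaggedSkeleton
setClass("TaggedSkeleton",
  representation(tags = "matrix", labels = "matrix", pixelSizeUm = "numeric"))

setValidity("TaggedSkeleton", function(object) {
  if (!identical(dim(object@tags), dim(object@labels)))
    return("tags and labels must share dimensions")
  if (any((object@tags > 0L) != (object@labels > 0L)))
    return("every tagged pixel must carry a nonzero label and vice versa")
  TRUE
})

#' Skeleton branch graph
#'
#' Nodes are merged junction clusters (8-connected junction pixels collapse
#' to a single node at their centroid), endpoints, and anchor nodes carrying
#' the self-edge of pure loops. Edges are maximal branches with their
#' ordered pixel paths and metric lengths (orthogonal step = pixel size,
#' diagonal step = sqrt(2) x pixel size).
#'
#' @slot nodes data.frame with columns nodeId, objectId, type
#'   ("junction"/"endpoint"/"anchor"), row, col (centroid, 1-based).
#' @slot edges data.frame with columns edgeId, objectId, fromNode, toNode,
#'   nPathPx, lengthUm.
#' @slot paths list of integer matrices (row, col), one ordered pixel path
#'   per edge, aligned with `edges`.
#' @slot pixelSizeUm microns per pixel edge.
#' @exportClass SkeletonGraph
setClass("SkeletonGraph",
  representation(nodes = "data.frame", edges = "data.frame",
                 paths = "list", pixelSizeUm = "numeric"))

setValidity("SkeletonGraph", function(object) {
  if (nrow(object@edges) != length(object@paths))
    return("one pixel path per edge required")
  TRUE
})

#' Synthetic-scene parameters
#'
#' Controls the ground-truthed micrograph generator: number, length and
#' branching of tubular objects, tube width, optics (Gaussian PSF) and a
#' Poisson-Gaussian noise model. Fully reproducible from `seed`; each
#' object draws from its own RNG substream so adding objects does not
#' perturb earlier ones.
#'
#' @slot imageSizePx frame edge, pixels (square frame).
#' @slot pixelSizeUm microns per pixel edge.
#' @slot nObjects number of tubular objects to place.
#' @slot branchingProb probability of sprouting a side branch at each
#'   interior anchor point of an object's trunk.
#' @slot lengthMeanUm,lengthSdUm trunk length distribution (truncated > 0).
#' @slot tubeWidthPx drawn tube width, pixels.
#' @slot psfSigmaPx Gaussian point-spread sigma, pixels (0 = no blur).
#' @slot backgroundLevel background intensity (8-bit scale).
#' @slot tubeIntensity peak tubule amplitude above background before blur.
#' @slot gaussianNoiseSd read-noise standard deviation (0 = off).
#' @slot poissonGain camera gain of the shot-noise model (0 = off).
#' @slot minSeparationPx minimum distance between distinct objects.
#' @slot seed RNG seed.
#' @exportClass SimParams
setClass("SimParams",
  representation(imageSizePx = "integer", pixelSizeUm = "numeric",
                 nObjects = "integer", branchingProb = "numeric",
                 lengthMeanUm = "numeric", lengthSdUm = "numeric",
                 tubeWidthPx = "numeric", psfSigmaPx = "numeric",
                 backgroundLevel = "numeric", tubeIntensity = "numeric",
                 gaussianNoiseSd = "numeric", poissonGain = "numeric",
                 minSeparationPx = "numeric", seed = "integer"),
  prototype(imageSizePx = 256L, pixelSizeUm = 0.1, nObjects = 20L,
            branchingProb = 0.3, lengthMeanUm = 4, lengthSdUm = 1.5,
            tubeWidthPx = 3, psfSigmaPx = 1, backgroundLevel = 20,
            tubeIntensity = 120, gaussianNoiseSd = 4, poissonGain = 1,
            minSeparationPx = 5, seed = 1L))

setValidity("SimParams", function(object) {
  if (object@imageSizePx < 32L) return("imageSizePx must be >= 32")
  if (object@pixelSizeUm <= 0) return("pixelSizeUm must be positive")
  if (object@nObjects < 0L) return("nObjects must be >= 0")
  if (object@branchingProb < 0 || object@branchingProb > 1)
    return("branchingProb must lie in [0, 1]")
  if (object@lengthMeanUm <= 0 || object@lengthSdUm < 0)
    return("length distribution must be positive")
  if (object@tubeWidthPx < 1) return("tubeWidthPx must be >= 1")
  if (object@psfSigmaPx < 0 || object@gaussianNoiseSd < 0 ||
      object@poissonGain < 0 || object@minSeparationPx < 0)
    return("optics/noise/separation parameters must be >= 0")
  if (object@backgroundLevel < 0 || object@tubeIntensity <= 0)
    return("intensity parameters out of range")
  TRUE
})

#' Run configuration for single and batch quantification
#'
#' @slot preprocess a [PreprocessParams-class] object.
#' @slot lengthMode `"total"` (per-object skeleton length, default) or
#'   `"longest-branch"`.
#' @slot pixelSizeUm microns per pixel edge applied to inputs read from disk.
#' @slot pruneSpursPx prune terminal junction-to-endpoint skeleton branches
#'   shorter than this many pixels (see [pruneSpurs()]); 0 disables.
#' @slot allowMixed allow rows with differing parameter fingerprints in one
#'   CSV (off by default).
#' @exportClass RunConfig
setClass("RunConfig",
  representation(preprocess = "PreprocessParams", lengthMode = "character",
                 pixelSizeUm = "numeric", pruneSpursPx = "numeric",
                 allowMixed = "logical"),
  prototype(lengthMode = "total", pixelSizeUm = 1, pruneSpursPx = 3,
            allowMixed = FALSE))

setValidity("RunConfig", function(object) {
  if (!object@lengthMode %in% c("total", "longest-branch"))
    return("lengthMode must be 'total' or 'longest-branch'")
  if (object@pixelSizeUm <= 0) return("pixelSizeUm must be positive")
  if (object@pruneSpursPx < 0) return("pruneSpursPx must be >= 0")
  TRUE
})
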