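#' @include AllGenerics.R
NULL

#' @describeIn pixels pixel raster of a GrayImage
#' @export
setMethod("pixels", "GrayImage", function(object) object@pixels)
#' @describeIn pixels logical raster of a BinaryMask
#' @export
setMethod("pixels", "BinaryMask", function(object) object@pixels)

#' @describeIn pixelSizeUm calibration of a GrayImage
#' @export
setMethod("pixelSizeUm", "GrayImage", function(object) object@pixelSizeUm)
#' @describeIn pixelSizeUm calibration of a BinaryMask
#' @export
setMethod("pixelSizeUm", "BinaryMask", function(object) object@pixelSizeUm)
#' @describeIn pixelSizeUm calibration of a TaggedSkeleton
#' @export
setMethod("pixelSizeUm", "TaggedSkeleton", function(object) object@pixelSizeUm)
#' @describeIn pixelSizeUm calibration of a SkeletonGraph
#' @export
setMethod("pixelSizeUm", "SkeletonGraph", function(object) object@pixelSizeUm)

#' @describeIn bitDepth bit depth of a GrayImage
#' @export
setMethod("bitDepth", "GrayImage", function(object) object@bitDepth)

#' @describeIn sourceId provenance of a GrayImage
#' @export
setMethod("sourceId", "GrayImage", function(object) object@sourceId)
#' @describeIn sourceId parent image id of a RegionOfInterest
#' @export
setMethod("sourceId", "RegionOfInterest", function(object) object@sourceId)

#' @describeIn validMask validity mask of a GrayImage
#' @export
setMethod("validMask", "GrayImage", function(object) object@validMask)
#' @describeIn validMask validity mask of a BinaryMask
#' @export
setMethod("validMask", "BinaryMask", function(object) object@validMask)

#' @describeIn skeletonTags tag raster of a TaggedSkeleton
#' @export
setMethod("skeletonTags", "TaggedSkeleton", function(object) object@tags)

#' @describeIn objectLabels label raster of a TaggedSkeleton
#' @export
setMethod("objectLabels", "TaggedSkeleton", function(object) object@labels)

#' @describeIn graphNodes nodes of a SkeletonGraph
#' @export
setMethod("graphNodes", "SkeletonGraph", function(object) object@nodes)

#' @describeIn graphEdges edges of a SkeletonGraph
#' @export
setMethod("graphEdges", "SkeletonGraph", function(object) object@edges)

#' @describeIn branchPaths pixel paths of a SkeletonGraph
#' @export
setMethod("branchPaths", "SkeletonGraph", function(object) object@paths)

#' @describeIn maskThreshold threshold of a BinaryMask
#' @export
setMethod("maskThreshold", "BinaryMask", function(object) object@threshold)

#' ROI id accessor
#' @param roi a RegionOfInterest
#' @return character scalar
#' @export
roiId <- function(roi) roi@roiId

setMethod("show", "GrayImage", function(object) {
  cat(sprintf("GrayImage '%s': %d x %d px, %d-bit, %.4g um/px, range [%g, %g]%s\n",
              object@sourceId, nrow(object@pixels), ncol(object@pixels),
              object@bitDepth, object@pixelSizeUm,
              min(object@pixels), max(object@pixels),
              if (length(object@validMask)) ", masked" else ""))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask: %d x %d px, %d foreground (%.2f%%), threshold %s\n",
              nrow(object@pixels), ncol(object@pixels), sum(object@pixels),
              100 * mean(object@pixels),
              ifelse(is.na(object@threshold), "none", format(object@threshold))))
})

setMethod("show", "TaggedSkeleton", function(object) {
  tg <- object@tags
  cat(sprintf(
    "TaggedSkeleton: %d objects; %d slab, %d endpoint, %d junction px\n",
    max(object@labels), sum(tg == TAG_SLAB), sum(tg == TAG_END),
    sum(tg == TAG_JUNC)))
})

setMethod("show", "SkeletonGraph", function(object) {
  nd <- object@nodes
  cat(sprintf(
    "SkeletonGraph: %d objects, %d junction nodes, %d endpoints, %d branches, total length %.3g um\n",
    length(unique(c(nd$objectId, object@edges$objectId))),
    sum(nd$type == "junction"), sum(nd$type == "endpoint"),
    nrow(object@edges), sum(object@edges$lengthUm)))
})

setMethod("show", "RegionOfInterest", function(object) {
  if (object@shapeType == "rectangle")
    cat(sprintf("ROI '%s' (source '%s'): rectangle origin (%g, %g), %g x %g px\n",
                object@roiId, object@sourceId, object@rect[1], object@rect[2],
                object@rect[3], object@rect[4]))
  else
    cat(sprintf("ROI '%s' (source '%s'): polygon, %d vertices\n",
                object@roiId, object@sourceId, nrow(object@vertices)))
})

setMethod("show", "RoiManifest", function(object) {
  cat(sprintf("RoiManifest: %d ROIs over %d image(s)\n",
              length(object@entries), length(object@imagePaths)))
})

setMethod("show", "SimParams", function(object) {
  cat(sprintf(
    "SimParams: %d px frame @ %.3g um/px, %d objects, branching %.2f, width %g px, PSF %g px, seed %d\n",
    object@imageSizePx, object@pixelSizeUm, object@nObjects,
    object@branchingProb, object@tubeWidthPx, object@psfSigmaPx, object@seed))
})
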