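#' @include AllClasses.R
NULL

#' Access the pixel raster
#' @param object a GrayImage, BinaryMask or TaggedSkeleton
#' @return the underlying matrix
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' Access the pixel-size calibration (microns per pixel edge)
#' @param object an object carrying a calibration
#' @return numeric scalar
#' @export
setGeneric("pixelSizeUm", function(object) standardGeneric("pixelSizeUm"))

#' Access the bit depth
#' @param object a GrayImage
#' @return 8 or 16
#' @export
setGeneric("bitDepth", function(object) standardGeneric("bitDepth"))

#' Access the provenance id
#' @param object a GrayImage or RegionOfInterest
#' @return character scalar
#' @export
setGeneric("sourceId", function(object) standardGeneric("sourceId"))

#' Access the ROI-validity mask
#' @param object a GrayImage or BinaryMask
#' @return logical matrix (possibly 0x0 when every pixel is valid)
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' Access the per-pixel skeleton tags
#' @param object a TaggedSkeleton
#' @return integer matrix (0 background, 1 slab, 2 endpoint, 3 junction)
#' @export
setGeneric("skeletonTags", function(object) standardGeneric("skeletonTags"))

#' Access the per-pixel object labels
#' @param object a TaggedSkeleton
#' @return integer matrix (0 = background)
#' @export
setGeneric("objectLabels", function(object) standardGeneric("objectLabels"))

#' Access graph nodes
#' @param object a SkeletonGraph
#' @return data.frame of nodes
#' @export
setGeneric("graphNodes", function(object) standardGeneric("graphNodes"))

#' Access graph edges (branches)
#' @param object a SkeletonGraph
#' @return data.frame of edges
#' @export
setGeneric("graphEdges", function(object) standardGeneric("graphEdges"))

#' Access per-edge ordered pixel paths
#' @param object a SkeletonGraph
#' @return list of (row, col) matrices aligned with [graphEdges()]
#' @export
setGeneric("branchPaths", function(object) standardGeneric("branchPaths"))

#' Access the applied binarization threshold
#' @param object a BinaryMask
#' @return numeric scalar (NA for masks not produced by thresholding)
#' @export
setGeneric("maskThreshold", function(object) standardGeneric("maskThreshold"))
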