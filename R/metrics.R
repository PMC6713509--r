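#' @include AllClasses.R utils.R
NULL

#' Measure each mitochondrial object
#'
#' One row per labelled skeleton object: total skeleton length, longest
#' branch length, mask-component area, branch / junction / endpoint counts,
#' and the network flag (at least one merged junction node). Object area is
#' taken from the 8-connected mask component containing the object's
#' skeleton; two skeleton objects sharing a mask component would violate
#' the thinning contract and raise an error.
#'
#' @param mask the [BinaryMask-class] the skeleton was derived from.
#' @param graph the [SkeletonGraph-class] of `skeletonize(mask)`.
#' @return data.frame with columns object_id, skeleton_length_um,
#'   longest_branch_um, area_um2, branch_count, junction_count,
#'   endpoint_count, is_network.
#' @export
measureObjects <- function(mask, graph) {
  psz <- graph@pixelSizeUm
  if (abs(psz - mask@pixelSizeUm) > 1e-12)
    stop("mask and graph calibrations differ")
  nd <- graph@nodes; ed <- graph@edges
  objIds <- sort(unique(c(nd$objectId, ed$objectId)))
  if (length(objIds) == 0L)
    return(data.frame(object_id = integer(0), skeleton_length_um = numeric(0),
                      longest_branch_um = numeric(0), area_um2 = numeric(0),
                      branch_count = integer(0), junction_count = integer(0),
                      endpoint_count = integer(0), is_network = logical(0)))
  maskLab <- label8(mask@pixels)
  compSize <- tabulate(maskLab[maskLab > 0L])
  compOf <- vapply(objIds, function(o) {
    i <- which(nd$objectId == o)[1L]
    comp <- maskLab[nd$pxRow[i], nd$pxCol[i]]
    if (comp == 0L)
      stop("skeleton object ", o, " lies outside the mask foreground")
    comp
  }, integer(1))
  if (anyDuplicated(compOf))
    stop("contract violation: two skeleton objects share one mask component")
  rows <- lapply(seq_along(objIds), function(i) {
    o <- objIds[i]
    e <- ed[ed$objectId == o, , drop = FALSE]
    n <- nd[nd$objectId == o, , drop = FALSE]
    jc <- sum(n$type == "junction")
    data.frame(object_id = o,
               skeleton_length_um = sum(e$lengthUm),
               longest_branch_um = if (nrow(e)) max(e$lengthUm) else 0,
               area_um2 = compSize[compOf[i]] * psz^2,
               branch_count = nrow(e),
               junction_count = jc,
               endpoint_count = sum(n$type == "endpoint"),
               is_network = jc >= 1L)
  })
  do.call(rbind, rows)
}

#' Summarize one cell into its per-ROI attribute row
#'
#' Computes the per-cell attributes: coverage (percentage of the valid ROI
#' area occupied by foreground), object count and its normalization per
#' 100 square microns, mean object length and area, network count, total
#' and per-network junction counts, and total branch count. With no
#' objects, all means are missing (NA), never 0.
#'
#' @param roiIdStr ROI identifier for the output row.
#' @param mask the cell's [BinaryMask-class]; a polygon crop's validity
#'   mask restricts the cell area to in-polygon pixels.
#' @param objects the data.frame from [measureObjects()].
#' @param sourceIdStr parent-image identifier.
#' @param lengthMode `"total"` (default: per-object total skeleton length)
#'   or `"longest-branch"`.
#' @param paramsFingerprint fingerprint string of the full parameter set
#'   (see [paramsFingerprint()]).
#' @return one-row data.frame in the documented CSV column order.
#' @export
summarizeCell <- function(roiIdStr, mask, objects, sourceIdStr = "",
                          lengthMode = c("total", "longest-branch"),
                          paramsFingerprint = "") {
  lengthMode <- match.arg(lengthMode)
  psz <- mask@pixelSizeUm
  validPx <- if (length(mask@validMask)) sum(mask@validMask)
             else length(mask@pixels)
  if (validPx == 0L) stop("zero-area ROI: ", roiIdStr)
  cellArea <- validPx * psz^2
  nObj <- nrow(objects)
  lens <- if (lengthMode == "total") objects$skeleton_length_um
          else objects$longest_branch_um
  nNet <- sum(objects$is_network)
  data.frame(
    roi_id = roiIdStr,
    source_id = sourceIdStr,
    cell_area_um2 = cellArea,
    mito_coverage_pct = 100 * sum(mask@pixels) / validPx,
    object_count = nObj,
    objects_per_100um2 = 100 * nObj / cellArea,
    mean_object_length_um = if (nObj) mean(lens) else NA_real_,
    mean_object_area_um2 = if (nObj) mean(objects$area_um2) else NA_real_,
    network_count = nNet,
    junction_count_total = if (nObj) sum(objects$junction_count) else 0L,
    mean_junctions_per_network =
      if (nNet) sum(objects$junction_count[objects$is_network]) / nNet
      else NA_real_,
    branch_count_total = if (nObj) sum(objects$branch_count) else 0L,
    threshold_used = mask@threshold,
    params_fingerprint = paramsFingerprint)
}

metricsColumns <- c("roi_id", "source_id", "cell_area_um2",
                    "mito_coverage_pct", "object_count", "objects_per_100um2",
                    "mean_object_length_um", "mean_object_area_um2",
                    "network_count", "junction_count_total",
                    "mean_junctions_per_network", "branch_count_total",
                    "threshold_used", "params_fingerprint")

#' Write per-cell metrics to CSV
#'
#' RFC-4180 CSV with a fixed, documented column order, one row per ROI,
#' floats at 6 significant digits, missing values as empty fields. All rows
#' must share a single parameter fingerprint (the batch-constancy guard)
#' unless `allowMixed`.
#'
#' @param rows data.frame of [summarizeCell()] rows.
#' @param path output path.
#' @param allowMixed permit rows with differing fingerprints.
#' @return the path, invisibly.
#' @export
writeMetricsCsv <- function(rows, path, allowMixed = FALSE) {
  if (nrow(rows)) {
    rows <- rows[, metricsColumns]
    if (!allowMixed && length(unique(rows$params_fingerprint)) > 1L)
      stop("rows carry mixed parameter fingerprints; ",
           "rerun with constant parameters or allowMixed = TRUE")
    num <- vapply(rows, is.numeric, logical(1))
    rows[num] <- lapply(rows[num], signif, digits = 6)
  } else {
    rows <- stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(metricsColumns))),
      metricsColumns)
  }
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a metrics CSV written by [writeMetricsCsv()]
#' @param path CSV path.
#' @return data.frame
#' @export
readMetricsCsv <- function(path) {
  utils::read.csv(path, colClasses = c(roi_id = "character",
                                       source_id = "character",
                                       params_fingerprint = "character"))
}
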