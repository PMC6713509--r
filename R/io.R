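#' @include AllClasses.R
NULL

#' Construct a GrayImage from a matrix
#'
#' @param pixels numeric matrix of intensities.
#' @param bitDepth 8 or 16.
#' @param pixelSizeUm microns per pixel edge.
#' @param sourceId provenance string.
#' @param validMask optional logical ROI-validity matrix.
#' @return a [GrayImage-class]
#' @export
grayImage <- function(pixels, bitDepth = 8L, pixelSizeUm = 1,
                      sourceId = "", validMask = matrix(logical(0), 0, 0)) {
  new("GrayImage", pixels = pixels, bitDepth = as.integer(bitDepth),
      pixelSizeUm = pixelSizeUm, sourceId = sourceId, validMask = validMask)
}

#' Construct a rectangular or polygonal ROI
#'
#' @param roiId unique id.
#' @param sourceId parent image id.
#' @param rect `(row0, col0, height, width)`, 0-based half-open (rectangle).
#' @param vertices n x 2 matrix of 0-based `(row, col)` vertices (polygon).
#' @return a [RegionOfInterest-class]
#' @export
roi <- function(roiId, sourceId, rect = NULL, vertices = NULL) {
  if (is.null(rect) == is.null(vertices))
    stop("provide exactly one of 'rect' or 'vertices'")
  if (!is.null(rect))
    new("RegionOfInterest", roiId = roiId, sourceId = sourceId,
        shapeType = "rectangle", rect = as.numeric(rect))
  else
    new("RegionOfInterest", roiId = roiId, sourceId = sourceId,
        shapeType = "polygon", vertices = vertices)
}

#' Read a calibrated grayscale TIFF
#'
#' Reads a single-channel 8- or 16-bit grayscale TIFF; intensities are kept
#' unmodified at their native bit depth. For multi-page stacks page 1 is
#' taken with a warning (the pipeline quantifies single best-focus planes).
#'
#' @param path file path.
#' @param pixelSizeUm microns per pixel edge. Defaults to 1 with a warning,
#'   since calibration is acquisition metadata the file rarely carries.
#' @return a [GrayImage-class]
#' @export
readImageTiff <- function(path, pixelSizeUm = NULL) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  if (is.null(pixelSizeUm)) {
    warning("no pixel size given for ", basename(path),
            "; defaulting to 1 um/px")
    pixelSizeUm <- 1
  }
  pg <- tiff::readTIFF(path, as.is = TRUE, all = TRUE, info = TRUE)
  if (length(pg) > 1L)
    warning(basename(path), " has ", length(pg), " pages; using page 1")
  px <- pg[[1L]]
  if (length(dim(px)) == 3L)
    stop("expected single-channel grayscale, got ", dim(px)[3L],
         " channels: ", path)
  bits <- attr(px, "bits.per.sample")
  if (is.null(bits)) bits <- if (max(px) > 255) 16L else 8L
  grayImage(matrix(as.numeric(px), nrow(px), ncol(px)),
            bitDepth = as.integer(bits), pixelSizeUm = pixelSizeUm,
            sourceId = basename(path))
}

#' Write a GrayImage to TIFF
#'
#' Round-trip safe: `readImageTiff(writeImageTiff(x))` reproduces the pixel
#' raster bit-identically at the image's bit depth.
#'
#' @param image a [GrayImage-class]
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeImageTiff <- function(image, path) {
  maxv <- 2^image@bitDepth - 1
  tiff::writeTIFF(round(image@pixels) / maxv, path,
                  bits.per.sample = image@bitDepth)
  invisible(path)
}

## Rasterize a polygon (0-based row,col vertices) onto an nr x nc grid,
## even-odd rule, boundary pixels included. Returns a logical matrix.
rasterizePolygon <- function(vertices, nr, nc) {
  vr <- vertices[, 1L] + 1  # to 1-based pixel centres
  vc <- vertices[, 2L] + 1
  n <- length(vr)
  mask <- matrix(FALSE, nr, nc)
  ## even-odd crossing test per pixel centre, vectorized over columns
  for (i in seq_len(nr)) {
    y <- i
    inside <- rep(FALSE, nc)
    j <- n
    xs <- seq_len(nc)
    for (k in seq_len(n)) {
      yk <- vr[k]; yj <- vr[j]
      if ((yk > y) != (yj > y)) {
        xint <- vc[k] + (y - yk) / (yj - yk) * (vc[j] - vc[k])
        inside <- xor(inside, xs < xint)
      }
      j <- k
    }
    mask[i, ] <- inside
  }
  ## include boundary pixels: walk each edge at sub-pixel steps
  for (k in seq_len(n)) {
    j <- if (k == n) 1L else k + 1L
    steps <- max(2L, ceiling(2 * max(abs(vr[j] - vr[k]), abs(vc[j] - vc[k]))))
    t <- seq(0, 1, length.out = steps)
    rr <- round(vr[k] + t * (vr[j] - vr[k]))
    cc <- round(vc[k] + t * (vc[j] - vc[k]))
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    mask[cbind(rr[ok], cc[ok])] <- TRUE
  }
  mask
}

## Bounding box (1-based, inclusive) of a ROI within an nr x nc image.
roiBounds <- function(r, nr, nc) {
  if (r@shapeType == "rectangle") {
    r0 <- r@rect[1L] + 1; c0 <- r@rect[2L] + 1
    list(r0 = r0, r1 = r0 + r@rect[3L] - 1, c0 = c0, c1 = c0 + r@rect[4L] - 1)
  } else {
    list(r0 = floor(min(r@vertices[, 1L])) + 1,
         r1 = ceiling(max(r@vertices[, 1L])) + 1,
         c0 = floor(min(r@vertices[, 2L])) + 1,
         c1 = ceiling(max(r@vertices[, 2L])) + 1)
  }
}

#' Crop one ROI from an image
#'
#' Rectangles return the exact sub-raster. Polygons return the bounding-box
#' sub-raster with pixels outside the polygon zeroed and a validity mask
#' attached, so downstream coverage uses only in-cell pixels. Calibration
#' is inherited.
#'
#' @param image a [GrayImage-class]
#' @param roi a [RegionOfInterest-class] lying fully inside the image.
#' @return a [GrayImage-class] crop with `sourceId` `<source>__<roiId>`.
#' @export
cropRoi <- function(image, roi) {
  nr <- nrow(image@pixels); nc <- ncol(image@pixels)
  b <- roiBounds(roi, nr, nc)
  if (b$r0 < 1 || b$c0 < 1 || b$r1 > nr || b$c1 > nc)
    stop("ROI '", roi@roiId, "' lies outside its ", nr, " x ", nc,
         " parent image")
  sub <- image@pixels[b$r0:b$r1, b$c0:b$c1, drop = FALSE]
  vm <- matrix(logical(0), 0, 0)
  if (roi@shapeType == "polygon") {
    full <- rasterizePolygon(roi@vertices, nr, nc)
    vm <- full[b$r0:b$r1, b$c0:b$c1, drop = FALSE]
    sub[!vm] <- 0
  }
  grayImage(sub, bitDepth = image@bitDepth, pixelSizeUm = image@pixelSizeUm,
            sourceId = paste0(roi@sourceId, "__", roi@roiId), validMask = vm)
}

#' Read an ROI manifest (JSON)
#'
#' Schema: `{"entries": [{"roi_id", "source_id", "shape": {"type":
#' "rectangle", "row0", "col0", "height", "width"} | {"type": "polygon",
#' "vertices": [[row, col], ...]}}, ...], "image_paths": {"<source_id>":
#' "<path>", ...}}`. Relative image paths resolve against the manifest's
#' directory.
#'
#' @param path JSON manifest path.
#' @return a [RoiManifest-class]
#' @export
readRoiManifest <- function(path) {
  j <- jsonlite::read_json(path)
  entries <- lapply(j$entries, function(e) {
    sh <- e$shape
    if (identical(sh$type, "rectangle"))
      roi(e$roi_id, e$source_id,
          rect = c(sh$row0, sh$col0, sh$height, sh$width))
    else if (identical(sh$type, "polygon"))
      roi(e$roi_id, e$source_id,
          vertices = do.call(rbind, lapply(sh$vertices,
                                           function(v) as.numeric(unlist(v)))))
    else stop("unknown ROI shape type: ", sh$type)
  })
  paths <- vapply(j$image_paths, as.character, character(1))
  rel <- !grepl("^(/|[A-Za-z]:)", paths)
  paths[rel] <- file.path(dirname(path), paths[rel])
  new("RoiManifest", entries = entries, imagePaths = paths)
}

#' Write an ROI manifest (JSON)
#' @param manifest a [RoiManifest-class]
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeRoiManifest <- function(manifest, path) {
  entries <- lapply(manifest@entries, function(r) {
    sh <- if (r@shapeType == "rectangle")
      list(type = "rectangle", row0 = r@rect[1L], col0 = r@rect[2L],
           height = r@rect[3L], width = r@rect[4L])
    else
      list(type = "polygon",
           vertices = lapply(seq_len(nrow(r@vertices)),
                             function(i) as.numeric(r@vertices[i, ])))
    list(roi_id = r@roiId, source_id = r@sourceId, shape = sh)
  })
  jsonlite::write_json(
    list(entries = entries, image_paths = as.list(manifest@imagePaths)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Batch-crop a manifest of ROIs to per-cell TIFFs
#'
#' One cropped TIFF per ROI, named `<source_id>__<roi_id>.tif`, in manifest
#' order; re-running overwrites deterministically. A failing ROI (e.g. out
#' of bounds) is logged and skipped; the run continues.
#'
#' @param manifest a [RoiManifest-class]
#' @param outDir output directory (created if absent).
#' @param pixelSizeUm calibration applied to the source images.
#' @return data.frame with columns roi_id, path, ok, message; attribute
#'   `"nFailed"` carries the failure count.
#' @export
batchCrop <- function(manifest, outDir, pixelSizeUm = 1) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cache <- new.env(parent = emptyenv())
  rows <- lapply(manifest@entries, function(r) {
    res <- tryCatch({
      key <- r@sourceId
      if (is.null(cache[[key]]))
        cache[[key]] <- readImageTiff(manifest@imagePaths[[key]],
                                      pixelSizeUm = pixelSizeUm)
      crop <- cropRoi(cache[[key]], r)
      out <- file.path(outDir, paste0(r@sourceId, "__", r@roiId, ".tif"))
      writeImageTiff(crop, out)
      data.frame(roi_id = r@roiId, path = out, ok = TRUE, message = "")
    }, error = function(e) {
      message("batchCrop: skipping ROI '", r@roiId, "': ", conditionMessage(e))
      data.frame(roi_id = r@roiId, path = NA_character_, ok = FALSE,
                 message = conditionMessage(e))
    })
    res
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(roi_id = character(0), path = character(0),
                         ok = logical(0), message = character(0))
  attr(out, "nFailed") <- sum(!out$ok)
  out
}
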