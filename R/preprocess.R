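#' @include AllClasses.R
NULL

#' Construct preprocessing parameters
#'
#' @param claheTiles CLAHE grid count per axis (default 8).
#' @param claheClip clip limit as a fraction of the tile histogram (0, 1].
#' @param medianRadiusPx median-filter radius in px (window `2r+1`).
#' @param unsharpRadiusPx Gaussian sigma of the unsharp mask, px.
#' @param unsharpAmount high-pass add-back weight:
#'   `out = in + amount * (in - Gaussian(in, radius))`, clipped to range.
#' @param thresholdMethod `"otsu"` (per-ROI) or `"fixed"`.
#' @param fixedThreshold intensity threshold used iff method is `"fixed"`.
#' @param minObjectPx remove foreground components smaller than this.
#' @return a [PreprocessParams-class]
#' @export
preprocessParams <- function(claheTiles = 8L, claheClip = 0.01,
                             medianRadiusPx = 1L, unsharpRadiusPx = 2,
                             unsharpAmount = 0.6,
                             thresholdMethod = c("otsu", "fixed"),
                             fixedThreshold = 0, minObjectPx = 4L) {
  new("PreprocessParams", claheTiles = as.integer(claheTiles),
      claheClip = claheClip, medianRadiusPx = as.integer(medianRadiusPx),
      unsharpRadiusPx = unsharpRadiusPx, unsharpAmount = unsharpAmount,
      thresholdMethod = match.arg(thresholdMethod),
      fixedThreshold = fixedThreshold, minObjectPx = as.integer(minObjectPx))
}

#' Enhance local contrast of a micrograph
#'
#' Applies, in order: contrast-limited adaptive histogram equalization
#' (CLAHE), median filtering, and an unsharp mask. Deterministic; output
#' keeps the input's shape and bit-depth scale. A constant image passes
#' through unchanged (all three steps are no-ops on flat input). Images
#' smaller than one CLAHE tile fall back to global histogram equalization
#' with a warning.
#'
#' @param image a [GrayImage-class]
#' @param params a [PreprocessParams-class]
#' @return the enhanced [GrayImage-class]
#' @export
enhanceImage <- function(image, params = preprocessParams()) {
  maxv <- 2^image@bitDepth - 1
  x <- image@pixels / maxv
  if (diff(range(x)) > 0) {
    nr <- nrow(x); nc <- ncol(x)
    tiles <- params@claheTiles
    ## EBImage's clip limit is expressed relative to the uniform bin height;
    ## claheClip is a fraction of the tile histogram, hence clip * bins.
    limit <- max(params@claheClip * 256, 1)
    if (tiles < 2) {
      ## a 1x1 tile grid is global histogram equalization by definition
      x <- as.matrix(EBImage::equalize(x, range = c(0, 1), levels = 256))
    } else if (nr >= 2 * tiles && nc >= 2 * tiles) {
      x <- as.matrix(EBImage::clahe(x, nx = tiles, ny = tiles,
                                    bins = 256, limit = limit))
    } else {
      warning("image smaller than the CLAHE tile grid; using global ",
              "histogram equalization")
      x <- as.matrix(EBImage::equalize(x, range = c(0, 1), levels = 256))
    }
    x[x < 0] <- 0; x[x > 1] <- 1
  }
  if (params@medianRadiusPx > 0)
    x <- as.matrix(EBImage::medianFilter(x, size = params@medianRadiusPx))
  if (params@unsharpAmount > 0 && params@unsharpRadiusPx > 0) {
    blur <- as.matrix(EBImage::gblur(x, sigma = params@unsharpRadiusPx))
    x <- x + params@unsharpAmount * (x - blur)
    x[x < 0] <- 0; x[x > 1] <- 1
  }
  grayImage(round(x * maxv), bitDepth = image@bitDepth,
            pixelSizeUm = image@pixelSizeUm, sourceId = image@sourceId,
            validMask = image@validMask)
}

#' Otsu threshold by exhaustive search over integer levels
#'
#' Scans every integer level `t` in `[1, 2^bitDepth - 1]` and returns the
#' one maximizing the between-class variance of the split
#' `{x < t} / {x >= t}`; ties break to the lowest level. Foreground is
#' `x >= t`, pixels at or above the returned level.
#'
#' @param x numeric matrix or vector of integer-valued intensities.
#' @param bitDepth 8 or 16.
#' @return the threshold level, or NA if the input has zero variance.
#' @export
otsuThreshold <- function(x, bitDepth = 8L) {
  v <- round(as.numeric(x))
  if (diff(range(v)) == 0) return(NA_real_)
  nlev <- 2^bitDepth
  h <- as.numeric(tabulate(v + 1L, nbins = nlev))  # levels 0..nlev-1
  lev <- 0:(nlev - 1)
  n <- sum(h)
  W <- cumsum(h)                         # pixels with level < t is W[t]
  M <- cumsum(h * lev)                   # intensity sum of levels < t
  mu <- M[nlev]
  t <- seq_len(nlev - 1L)                # candidate thresholds 1..nlev-1
  w0 <- W[t]; m0 <- M[t]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bc <- rep(-Inf, nlev - 1L)
  bc[valid] <- (mu * w0[valid] - m0[valid] * n)^2 /
    (as.numeric(w0[valid]) * w1[valid])
  as.numeric(t[which.max(bc)])           # first max = lowest tied level
}

#' Binarize an enhanced image
#'
#' Thresholds with per-ROI Otsu (default) or a fixed level, then removes
#' connected foreground components (8-connectivity) smaller than
#' `minObjectPx`. When a validity mask is attached (polygon crops), pixels
#' outside the ROI are never foreground and are excluded from the Otsu
#' histogram. A zero-variance image under Otsu yields an empty mask with a
#' warning.
#'
#' @param image a [GrayImage-class] (normally the output of [enhanceImage()]).
#' @param params a [PreprocessParams-class]
#' @return a [BinaryMask-class]; the applied threshold is recorded in the
#'   object and available via [maskThreshold()].
#' @export
binarizeImage <- function(image, params = preprocessParams()) {
  px <- image@pixels
  hasVm <- length(image@validMask) > 0L
  if (params@thresholdMethod == "otsu") {
    sample <- if (hasVm) px[image@validMask] else px
    thr <- otsuThreshold(sample, image@bitDepth)
    if (is.na(thr)) {
      warning("zero intensity variance: no Otsu threshold exists; ",
              "returning an empty mask")
      fg <- matrix(FALSE, nrow(px), ncol(px))
      return(new("BinaryMask", pixels = fg, pixelSizeUm = image@pixelSizeUm,
                 threshold = NA_real_, validMask = image@validMask))
    }
    fg <- px >= thr
  } else {
    thr <- params@fixedThreshold
    fg <- px >= thr
  }
  if (hasVm) fg <- fg & image@validMask
  if (params@minObjectPx > 0 && any(fg)) {
    lab <- label8(fg)
    sizes <- tabulate(lab[lab > 0L])
    small <- which(sizes < params@minObjectPx)
    if (length(small)) fg[lab %in% small] <- FALSE
  }
  new("BinaryMask", pixels = fg, pixelSizeUm = image@pixelSizeUm,
      threshold = as.numeric(thr), validMask = image@validMask)
}
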