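#' @include AllClasses.R utils.R
NULL

#' Construct synthetic-scene parameters
#'
#' Defaults emulate a sparse field of mitochondrial tubules as seen with an
#' outer-membrane GFP reporter under a high-NA oil objective: ~0.1 um
#' pixels, tubules a few microns long drawn 3 px wide, a ~1 px Gaussian
#' PSF, and mixed Poisson-Gaussian camera noise on an 8-bit scale.
#'
#' @param imageSizePx,pixelSizeUm,nObjects,branchingProb,lengthMeanUm,lengthSdUm,tubeWidthPx,psfSigmaPx,backgroundLevel,tubeIntensity,gaussianNoiseSd,poissonGain,minSeparationPx,seed
#'   see [SimParams-class].
#' @return a [SimParams-class]
#' @export
simParams <- function(imageSizePx = 256L, pixelSizeUm = 0.1, nObjects = 20L,
                      branchingProb = 0.3, lengthMeanUm = 4, lengthSdUm = 1.5,
                      tubeWidthPx = 3, psfSigmaPx = 1, backgroundLevel = 20,
                      tubeIntensity = 120, gaussianNoiseSd = 4,
                      poissonGain = 1, minSeparationPx = 5, seed = 1L) {
  new("SimParams", imageSizePx = as.integer(imageSizePx),
      pixelSizeUm = pixelSizeUm, nObjects = as.integer(nObjects),
      branchingProb = branchingProb, lengthMeanUm = lengthMeanUm,
      lengthSdUm = lengthSdUm, tubeWidthPx = tubeWidthPx,
      psfSigmaPx = psfSigmaPx, backgroundLevel = backgroundLevel,
      tubeIntensity = tubeIntensity, gaussianNoiseSd = gaussianNoiseSd,
      poissonGain = poissonGain, minSeparationPx = minSeparationPx,
      seed = as.integer(seed))
}

## Deterministic substream seed derived from (seed, k); stays below 2^31.
substreamSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 9973) %% 2147483647)
}

## Disk stamp offsets for a given tube width (diameter) in px.
diskOffsets <- function(widthPx) {
  rad <- widthPx / 2
  rr <- -ceiling(rad):ceiling(rad)
  g <- expand.grid(dr = rr, dc = rr)
  g[sqrt(g$dr^2 + g$dc^2) <= rad + 1e-9, , drop = FALSE]
}

## Stamp a polyline (n x 2 matrix of row, col) onto a logical frame.
stampTube <- function(frame, pts, offs) {
  nr <- nrow(frame); nc <- ncol(frame)
  rp <- round(pts[, 1L]); cp <- round(pts[, 2L])
  for (k in seq_len(nrow(offs))) {
    rr <- rp + offs$dr[k]; cc <- cp + offs$dc[k]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    frame[cbind(rr[ok], cc[ok])] <- TRUE
  }
  frame
}

## Smoothed random-walk polyline: unit steps, turning angle bounded by
## maxTurn, avoiding the frame border, `avoid` pixels, and its own earlier
## path (points more than `lag` steps back must stay >= selfDist away).
## Returns an n x 2 matrix (possibly shorter than requested if boxed in).
walkPolyline <- function(start, theta0, nSteps, nr, nc, avoid = NULL,
                         ownPts = NULL, maxTurn = pi / 6, margin = 3,
                         selfDist = 7, lag = 12, grace = 0L) {
  pts <- matrix(0, nSteps + 1L, 2L)
  pts[1L, ] <- start
  theta <- theta0
  nOk <- 1L
  for (t in seq_len(nSteps)) {
    placed <- FALSE
    for (try in 1:12) {
      ## resample within the turning bound when blocked; walks that cannot
      ## comply truncate rather than bend beyond the bound
      turn <- stats::runif(1, -maxTurn, maxTurn)
      th <- theta + turn
      cand <- pts[nOk, ] + c(sin(th), cos(th))
      if (cand[1L] < margin || cand[1L] > nr - margin + 1 ||
          cand[2L] < margin || cand[2L] > nc - margin + 1) next
      rc <- round(cand)
      if (!is.null(avoid) && avoid[rc[1L], rc[2L]]) next
      ## self-avoidance: keep clear of own points more than `lag` steps
      ## back and of `ownPts` (other segments of the same object); the
      ## first `grace` steps skip the ownPts check so a side branch can
      ## leave its parent trunk
      prior <- rbind(if (nOk > lag) pts[seq_len(nOk - lag), , drop = FALSE],
                     if (t > grace) ownPts)
      if (!is.null(prior) && nrow(prior) &&
          min((prior[, 1L] - cand[1L])^2 + (prior[, 2L] - cand[2L])^2) <
            selfDist^2) next
      theta <- th; nOk <- nOk + 1L; pts[nOk, ] <- cand; placed <- TRUE
      break
    }
    if (!placed) break
  }
  pts[seq_len(nOk), , drop = FALSE]
}

#' Render one ground-truthed synthetic micrograph
#'
#' Places `nObjects` smoothed random-walk tubules with rejection sampling
#' enforcing the minimum inter-object separation, sprouts side branches
#' (degree-3 junctions) with probability `branchingProb` per interior
#' anchor, rasterizes at the drawn tube width, blurs with a Gaussian PSF,
#' and adds Poisson shot noise and Gaussian read noise. Fully reproducible:
#' each object draws from its own substream of `seed`, so enlarging
#' `nObjects` does not perturb earlier objects.
#'
#' @param params a [SimParams-class]
#' @return list with elements `image` (noisy [GrayImage-class]),
#'   `truthMask` (noiseless [BinaryMask-class] render of the drawn tubes),
#'   and `truth`, a list with `segments` (polylines, um), `junctions`
#'   (data.frame row, col, degree in px coordinates), `objectMembership`
#'   (segment -> object id), `trueObjectCount`, `trueJunctionCount`,
#'   `trueCoveragePct`, `trueTotalLengthUm`, and `snr` (peak above
#'   background over noise sd at background).
#' @export
simulateImage <- function(params) {
  stopifnot(is(params, "SimParams"))
  n <- params@imageSizePx
  psz <- params@pixelSizeUm
  offs <- diskOffsets(params@tubeWidthPx)
  sep <- params@minSeparationPx
  sepBrush <- EBImage::makeBrush(2L * ceiling(sep) + 1L, shape = "disc")

  truthMask <- matrix(FALSE, n, n)
  occDil <- matrix(FALSE, n, n)   # occupied, dilated by the separation
  segments <- list(); membership <- integer(0)
  junctions <- data.frame(row = numeric(0), col = numeric(0),
                          degree = integer(0))
  nJunctions <- 0L

  for (i in seq_len(params@nObjects)) {
    set.seed(substreamSeed(params@seed, i))
    placedObj <- FALSE
    for (attempt in 1:30) {
      lenUm <- -1
      while (lenUm <= 0)
        lenUm <- stats::rnorm(1, params@lengthMeanUm, params@lengthSdUm)
      nSteps <- max(3L, round(lenUm / psz))
      start <- stats::runif(2, 8, n - 7)
      trunk <- walkPolyline(start, stats::runif(1, 0, 2 * pi), nSteps,
                            n, n, avoid = occDil)
      if (nrow(trunk) < max(4L, nSteps %/% 3L)) next  # boxed in; retry
      objSegs <- list(trunk)
      objJunc <- data.frame(row = numeric(0), col = numeric(0),
                            degree = integer(0))
      ## side branches at interior anchors; anchors keep >= 12 steps of
      ## trunk on either side so all three arms of the junction protrude
      ## resolvably beyond the merged tube zone
      anchorIdx <- if (nrow(trunk) >= 26L)
        seq(13L, nrow(trunk) - 12L, by = 8L) else integer(0)
      for (a in anchorIdx) {
        if (stats::runif(1) >= params@branchingProb) next
        dirv <- trunk[min(a + 1L, nrow(trunk)), ] - trunk[a - 1L, ]
        thTrunk <- atan2(dirv[1L], dirv[2L])
        thBr <- thTrunk + sample(c(-1, 1), 1L) * stats::runif(1, pi / 3,
                                                              2 * pi / 3)
        ## a side branch must protrude well beyond the parent tube (> 2 tube
        ## widths past the merge zone) or its junction is unresolvable and
        ## would corrupt the ground truth
        brSteps <- max(12L, round(nrow(trunk) * stats::runif(1, 0.25, 0.5)))
        ownPrior <- do.call(rbind, objSegs)
        ## the grace window lasts until a 60-degree branch has cleared the
        ## self-avoidance radius of its parent trunk
        br <- walkPolyline(trunk[a, ], thBr, brSteps, n, n, avoid = occDil,
                           ownPts = ownPrior, grace = 9L)
        if (nrow(br) < 12L) next
        ## the grace window skipped self-avoidance: reject the branch if its
        ## early course runs into object parts away from the anchor, which
        ## would fuse tubes and corrupt the junction ground truth
        early <- br[2:min(10L, nrow(br)), , drop = FALSE]
        awayFromAnchor <- (ownPrior[, 1L] - trunk[a, 1L])^2 +
                          (ownPrior[, 2L] - trunk[a, 2L])^2 > 16
        if (any(awayFromAnchor)) {
          op <- ownPrior[awayFromAnchor, , drop = FALSE]
          d2 <- outer(early[, 1L], op[, 1L], "-")^2 +
                outer(early[, 2L], op[, 2L], "-")^2
          if (min(d2) < 4^2) next
        }
        objSegs[[length(objSegs) + 1L]] <- br
        objJunc <- rbind(objJunc,
                         data.frame(row = trunk[a, 1L], col = trunk[a, 2L],
                                    degree = 3L))
      }
      objMask <- matrix(FALSE, n, n)
      for (sg in objSegs) objMask <- stampTube(objMask, sg, offs)
      if (any(objMask & occDil)) next
      ## accept
      truthMask <- truthMask | objMask
      occDil <- occDil |
        (as.matrix(EBImage::dilate(EBImage::Image(objMask * 1), sepBrush)) > 0.5)
      for (sg in objSegs) {
        segments[[length(segments) + 1L]] <- sg * psz
        membership <- c(membership, i)
      }
      junctions <- rbind(junctions, objJunc)
      nJunctions <- nJunctions + nrow(objJunc)
      placedObj <- TRUE
      break
    }
    if (!placedObj)
      stop("could not place object ", i, " after 30 attempts; ",
           "use a larger frame or fewer/shorter objects")
  }

  ## optics + noise
  signal <- matrix(as.numeric(truthMask), n, n)
  if (params@psfSigmaPx > 0)
    signal <- as.matrix(EBImage::gblur(signal, sigma = params@psfSigmaPx))
  img0 <- params@backgroundLevel + params@tubeIntensity * signal
  set.seed(substreamSeed(params@seed, 999983L))
  img <- img0
  if (params@poissonGain > 0)
    img <- params@poissonGain * stats::rpois(length(img0),
                                             img0 / params@poissonGain)
  if (params@gaussianNoiseSd > 0)
    img <- img + stats::rnorm(length(img0), 0, params@gaussianNoiseSd)
  img <- matrix(pmin(pmax(round(img), 0), 255), n, n)

  noiseSd <- sqrt(params@poissonGain * params@backgroundLevel +
                  params@gaussianNoiseSd^2)
  peak <- params@tubeIntensity * max(signal)
  totalLenUm <- sum(vapply(segments, function(sg)
    sum(sqrt(rowSums(diff(sg)^2))), numeric(1)))

  list(
    image = grayImage(img, bitDepth = 8L, pixelSizeUm = psz,
                      sourceId = sprintf("sim_seed%d", params@seed)),
    truthMask = new("BinaryMask", pixels = truthMask, pixelSizeUm = psz),
    truth = list(
      segments = segments, junctions = junctions,
      objectMembership = membership,
      trueObjectCount = params@nObjects,
      trueJunctionCount = nJunctions,
      trueCoveragePct = 100 * mean(truthMask),
      trueTotalLengthUm = totalLenUm,
      snr = if (noiseSd > 0) peak / noiseSd else Inf))
}

#' Generate a matched fused / fragmented condition pair
#'
#' The fused member has few, long, branched tubules (interconnected
#' networks); the fragmented member has many short unbranched tubules.
#' The fragmented total drawn length is iteratively rescaled so the two
#' true coverages agree within 5% relative, emulating equal mitochondrial
#' content in opposite fission/fusion states.
#'
#' @param base a [SimParams-class] carrying frame, optics, noise and seed;
#'   `base@lengthMeanUm * base@nObjects` sets the total tubule length.
#' @param fusedN object count of the fused member (few).
#' @param fragmentedN object count of the fragmented member (many;
#'   must exceed `fusedN`).
#' @param fusedBranching branching probability of the fused member.
#' @return list with elements `fused` and `fragmented`, each a
#'   [simulateImage()] result.
#' @export
simulateConditionPair <- function(base, fusedN = 5L, fragmentedN = 50L,
                                  fusedBranching = 0.5) {
  if (fusedN >= fragmentedN)
    stop("fusedN must be smaller than fragmentedN")
  totalLenUm <- base@lengthMeanUm * base@nObjects
  fusedP <- base
  fusedP@nObjects <- as.integer(fusedN)
  fusedP@branchingProb <- fusedBranching
  fusedP@lengthMeanUm <- totalLenUm / fusedN
  fusedP@lengthSdUm <- 0.25 * fusedP@lengthMeanUm
  fusedP@seed <- substreamSeed(base@seed, 101L)
  fused <- simulateImage(fusedP)

  fragP <- base
  fragP@nObjects <- as.integer(fragmentedN)
  fragP@branchingProb <- 0
  fragP@lengthMeanUm <- totalLenUm / fragmentedN
  fragP@lengthSdUm <- 0.25 * fragP@lengthMeanUm
  fragP@seed <- substreamSeed(base@seed, 202L)
  fragmented <- simulateImage(fragP)
  for (it in 1:4) {
    rel <- abs(fragmented$truth$trueCoveragePct -
               fused$truth$trueCoveragePct) / fused$truth$trueCoveragePct
    if (rel <= 0.05) break
    fragP@lengthMeanUm <- fragP@lengthMeanUm *
      fused$truth$trueCoveragePct / fragmented$truth$trueCoveragePct
    fragP@lengthSdUm <- 0.25 * fragP@lengthMeanUm
    fragmented <- simulateImage(fragP)
  }
  list(fused = fused, fragmented = fragmented)
}
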