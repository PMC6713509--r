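## Fixture builders and independent brute-force oracles used across the
## suite. Oracles deliberately use different mechanics from the package
## implementation (explicit per-pixel loops and igraph component analysis
## instead of raster tracing).

mkMask <- function(m, psz = 1) new("BinaryMask", pixels = m, pixelSizeUm = psz)

## two 21-px perpendicular lines sharing their centre pixel
plusCrossMask <- function() {
  m <- matrix(FALSE, 31, 31)
  m[16, 6:26] <- TRUE
  m[6:26, 16] <- TRUE
  m
}

## two 21-px vertical lines joined at their 11th pixel by a 9-px rung
hShapeMask <- function() {
  m <- matrix(FALSE, 31, 31)
  m[6:26, 5] <- TRUE
  m[6:26, 15] <- TRUE
  m[16, 6:14] <- TRUE
  m
}

## perfect diagonal of n pixels
diagonalMask <- function(n = 11) {
  m <- matrix(FALSE, n + 4, n + 4)
  for (i in seq_len(n)) m[i + 2, i + 2] <- TRUE
  m
}

## filled annulus (ring) centred in a 41 x 41 frame
annulusMask <- function() {
  d <- outer(1:41, 1:41, function(r, c) sqrt((r - 21)^2 + (c - 21)^2))
  d >= 8 & d <= 14
}

## per-pixel 8-neighbour count by explicit loops (oracle for tagging)
oracleNeighborCounts <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  out <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    n <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc && fg[rr, cc])
        n <- n + 1L
    }
    out[r, c] <- n
  }
  out
}

## expected tag raster from the neighbour-count rule
oracleTags <- function(fg) {
  nb <- oracleNeighborCounts(fg)
  tg <- matrix(0L, nrow(fg), ncol(fg))
  tg[fg & nb <= 1L] <- 2L   # endpoint
  tg[fg & nb == 2L] <- 1L   # slab
  tg[fg & nb >= 3L] <- 3L   # junction
  tg
}

## Otsu oracle: exhaustive scan minimizing the within-class weighted
## variance of the {x < t} / {x >= t} split (the complementary formulation
## to maximizing between-class variance); first minimum wins.
oracleOtsu <- function(v, bitDepth = 8L) {
  v <- round(as.numeric(v))
  if (diff(range(v)) == 0) return(NA_real_)
  best <- Inf; bestT <- NA_real_
  for (t in 1:(2^bitDepth - 1)) {
    lo <- v[v < t]; hi <- v[v >= t]
    if (!length(lo) || !length(hi)) next
    ## total within-class sum of squares (var of a single value is 0)
    vlo <- if (length(lo) > 1) stats::var(lo) * (length(lo) - 1) else 0
    vhi <- if (length(hi) > 1) stats::var(hi) * (length(hi) - 1) else 0
    wv <- vlo + vhi
    if (wv < best - 1e-9) { best <- wv; bestT <- t }
  }
  bestT
}

## Graph-count oracle built on igraph components over the pixel adjacency
## graph. Returns junction-node, endpoint and edge counts after the same
## merge rules the package documents: 8-connected junction pixels form one
## node; junction-junction connectors of <= mergeGapPx slab pixels are
## contracted.
oracleGraphCounts <- function(fg, mergeGapPx = 2) {
  nr <- nrow(fg); nc <- ncol(fg)
  idx <- which(fg)
  if (!length(idx)) return(list(nJunction = 0L, nEndpoint = 0L, nEdges = 0L))
  pos <- seq_along(idx)
  lut <- integer(nr * nc); lut[idx] <- pos
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  ep <- NULL
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    r2 <- r + dr; c2 <- c + dc
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- lut[j] > 0L
    ep <- rbind(ep, cbind(pos[ok][hit], lut[j][hit]))
  }
  g <- igraph::graph_from_edgelist(ep[ep[, 1] < ep[, 2], , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  deg <- igraph::degree(g)
  jpx <- which(deg >= 3L)
  epx <- which(deg <= 1L)
  ## junction clusters
  nJ <- 0L; clusterOf <- integer(length(idx))
  if (length(jpx)) {
    sub <- igraph::induced_subgraph(g, jpx)
    memb <- igraph::components(sub)$membership
    nJ <- max(memb)
    clusterOf[jpx] <- memb
  }
  ## slab/endpoint segments
  nonj <- setdiff(pos, jpx)
  nSeg <- 0L; nContract <- 0L; nIsolated <- 0L
  parent <- seq_len(max(nJ, 1L))
  findp <- function(x) { x <- as.integer(x)
    while (parent[x] != x) x <- parent[x]; x }
  if (length(nonj)) {
    sub <- igraph::induced_subgraph(g, nonj)
    memb <- igraph::components(sub)$membership
    nSeg <- max(memb)
    for (s in seq_len(nSeg)) {
      segPos <- nonj[memb == s]
      ## clusters adjacent to this segment
      nb <- unique(unlist(lapply(segPos, function(p)
        clusterOf[as.integer(igraph::neighbors(g, p))])))
      nb <- nb[nb > 0L]
      if (length(segPos) == 1L && length(nb) == 0L &&
          deg[segPos] == 0L) {
        nIsolated <- nIsolated + 1L          # lone pixel: node, no edge
      } else if (length(nb) == 2L && length(segPos) <= mergeGapPx) {
        nContract <- nContract + 1L          # short junction-junction link
        a <- findp(nb[1L]); b <- findp(nb[2L])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
    }
  }
  nJmerged <- if (nJ) length(unique(vapply(seq_len(as.integer(nJ)), findp,
                                           integer(1))))
              else 0L
  list(nJunction = as.integer(nJmerged), nEndpoint = length(epx),
       nEdges = as.integer(nSeg - nIsolated - nContract))
}

## random thin skeleton: threshold smoothed noise, then thin it
randomThinSkeleton <- function(seed, size = 32L) {
  set.seed(seed)
  x <- matrix(stats::runif(size * size), size, size)
  x <- as.matrix(EBImage::gblur(x, sigma = 2))
  fg <- x > stats::quantile(x, 0.75)
  pixels(skeletonize(mkMask(fg)))
}

## simple deterministic GrayImage from a matrix
mkImage <- function(m, bitDepth = 8L, psz = 1) {
  grayImage(m, bitDepth = bitDepth, pixelSizeUm = psz, sourceId = "fixture")
}
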