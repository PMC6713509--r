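## Shared low-level helpers: padded matrix shifts, 8-neighbour counting,
## 8-connected component labeling, FNV-1a hashing.

## Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shiftMatrix <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr); cs <- seq_len(nc)
  srcR <- rs - dr; srcC <- cs - dc
  okR <- srcR >= 1L & srcR <= nr
  okC <- srcC >= 1L & srcC <= nc
  out[rs[okR], cs[okC]] <- m[srcR[okR], srcC[okC]]
  out
}

## Offsets of the 8-neighbourhood, clockwise from north.
NEIGH8 <- cbind(
  dr = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
  dc = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
)

## Per-pixel count of foreground 8-neighbours of a logical matrix.
neighborCount8 <- function(fg) {
  fgI <- matrix(as.integer(fg), nrow(fg), ncol(fg))
  acc <- matrix(0L, nrow(fg), ncol(fg))
  for (k in seq_len(nrow(NEIGH8)))
    acc <- acc + shiftMatrix(fgI, NEIGH8[k, 1L], NEIGH8[k, 2L])
  acc
}

## 8-connected component labeling. Labels 1..K assigned in raster-scan
## order (top-left origin, row-major) of each component's first pixel.
## Returns an integer matrix, 0 = background.
label8 <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  idx <- which(fg)
  if (length(idx) == 0L) return(lab)
  pos <- match(idx, idx)  # 1..n over foreground pixels
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  ## edges to 4 forward neighbours (E, SW, S, SE) cover all 8-adjacency pairs
  edges <- integer(0)
  lut <- integer(nr * nc); lut[idx] <- pos
  for (off in list(c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))) {
    r2 <- r + off[1L]; c2 <- c + off[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- lut[j] > 0L
    if (any(hit))
      edges <- c(edges, rbind(pos[ok][hit], lut[j][hit]))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  ## raster order: row-major position of each component's first pixel
  raster <- (r - 1L) * nc + c
  firstRaster <- tapply(raster, comp, min)
  newId <- integer(length(firstRaster))
  newId[order(firstRaster)] <- seq_along(firstRaster)
  lab[idx] <- newId[comp]
  lab
}

## FNV-1a 32-bit hash of a character scalar, as 8 hex digits.
## Used for parameter-set fingerprints; implemented here to keep the
## fingerprint stable across platforms without external hashing deps.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    ## xor the byte into the low 8 bits (h may exceed .Machine$integer.max)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    ## 32-bit modular multiply by 16777619 in double precision via splitting
    lo <- h %% 65536; hi <- h %/% 65536
    h <- ((lo * 16777619) %% 4294967296 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

## Metric length of an ordered path (n x 2 matrix of row,col): the sum of
## Euclidean step lengths, which for unit pixel steps is the standard
## orthogonal = 1 / diagonal = sqrt(2) rule; terminal steps onto a merged
## junction node's centroid use the exact Euclidean distance.
pathLengthUm <- function(path, pixelSizeUm) {
  if (is.null(path) || nrow(path) < 2L) return(0)
  dr <- diff(path[, 1L]); dc <- diff(path[, 2L])
  sum(sqrt(dr^2 + dc^2)) * pixelSizeUm
}
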