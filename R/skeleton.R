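#' @include AllClasses.R utils.R
NULL

## Neighbour rasters P2..P9 (clockwise from north) of a 0/1 matrix.
## Pk(r, c) = fg(r + dr_k, c + dc_k).
zsNeighbors <- function(fgI) {
  lapply(seq_len(8L), function(k)
    shiftMatrix(fgI, -NEIGH8[k, 1L], -NEIGH8[k, 2L]))
}

## Crossing number A: 0->1 transitions around the ordered neighbour circle.
zsTransitions <- function(P) {
  A <- matrix(0L, nrow(P[[1L]]), ncol(P[[1L]]))
  for (k in seq_len(8L)) {
    nxt <- if (k == 8L) 1L else k + 1L
    A <- A + (P[[k]] == 0L) * (P[[nxt]] == 1L)
  }
  A
}

#' Topology-preserving 2D skeletonization
#'
#' Reduces a binary mask to a 1-px-wide skeleton by Zhang-Suen parallel
#' thinning, followed by a deterministic cleanup that removes simple pixels
#' from any residual fully-foreground 2x2 block. Connected-component count
#' and loop count are preserved: a component that parallel thinning would
#' delete entirely (e.g. an isolated 2x2 block) is restored as its single
#' most central pixel.
#'
#' @param mask a [BinaryMask-class]
#' @return a [BinaryMask-class] holding the skeleton (threshold inherited).
#' @export
skeletonize <- function(mask) {
  fg <- mask@pixels
  nr <- nrow(fg); nc <- ncol(fg)
  compBefore <- label8(fg)
  fgI <- matrix(as.integer(fg), nr, nc)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      P <- zsNeighbors(fgI)
      B <- Reduce(`+`, P)
      A <- zsTransitions(P)
      ## P2=N, P4=E, P6=S, P8=W
      if (sub == 1L)
        cond <- P[[1L]] * P[[3L]] * P[[5L]] == 0L &
                P[[3L]] * P[[5L]] * P[[7L]] == 0L
      else
        cond <- P[[1L]] * P[[3L]] * P[[7L]] == 0L &
                P[[1L]] * P[[5L]] * P[[7L]] == 0L
      del <- fgI == 1L & B >= 2L & B <= 6L & A == 1L & cond
      if (any(del)) { fgI[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  ## cleanup: sequentially delete redundant pixels (Yokoi/Hilditch
  ## connectivity number 1 with >= 2 neighbours). Parallel thinning leaves
  ## staircase-corner pixels whose Rutovitz crossing number is 2 although
  ## their removal preserves topology; left in place they would be tagged
  ## as spurious junctions on every curved tubule.
  nc8 <- function(r, c) {
    ## neighbours counter-clockwise from east in the Yokoi convention
    ord <- matrix(c(0L, 1L, -1L, 1L, -1L, 0L, -1L, -1L,
                    0L, -1L, 1L, -1L, 1L, 0L, 1L, 1L), ncol = 2L,
                  byrow = TRUE)
    x <- vapply(seq_len(8L), function(k) {
      rr <- r + ord[k, 1L]; cc <- c + ord[k, 2L]
      if (rr < 1L || rr > nr || cc < 1L || cc > nc) 0L else fgI[rr, cc]
    }, integer(1))
    xb <- 1L - x
    idx <- function(k) ((k - 1L) %% 8L) + 1L
    sum(vapply(c(1L, 3L, 5L, 7L), function(k)
      xb[k] - xb[k] * xb[idx(k + 1L)] * xb[idx(k + 2L)], integer(1)))
  }
  repeat {
    B <- neighborCount8(fgI == 1L)
    cand <- which(fgI == 1L & B >= 2L)
    cand <- cand[order(rasterKey(cand, nr, nc))]
    removedAny <- FALSE
    for (i in cand) {
      r <- ((i - 1L) %% nr) + 1L; c <- ((i - 1L) %/% nr) + 1L
      win <- vapply(seq_len(8L), function(k) {
        rr <- r + NEIGH8[k, 1L]; cc <- c + NEIGH8[k, 2L]
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) 0L else fgI[rr, cc]
      }, integer(1))
      if (sum(win) >= 2L && nc8(r, c) == 1L) {
        fgI[r, c] <- 0L
        removedAny <- TRUE
      }
    }
    if (!removedAny) break
  }
  ## safety net: no 2x2 block may remain entirely foreground
  repeat {
    blk <- fgI[-nr, -nc] & fgI[-1L, -nc] & fgI[-nr, -1L] & fgI[-1L, -1L]
    if (!any(blk)) break
    hit <- which(blk, arr.ind = TRUE)[1L, ]
    removed <- FALSE
    for (d in list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))) {
      r <- hit[1L] + d[1L]; c <- hit[2L] + d[2L]
      ## simple + not an endpoint: removal keeps local topology
      win <- vapply(seq_len(8L), function(k) {
        rr <- r + NEIGH8[k, 1L]; cc <- c + NEIGH8[k, 2L]
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) 0L else fgI[rr, cc]
      }, integer(1))
      B <- sum(win)
      A <- sum(win == 0L & win[c(2:8, 1L)] == 1L)
      if (A == 1L && B >= 2L) { fgI[r, c] <- 0L; removed <- TRUE; break }
    }
    if (!removed) break  # no deletable pixel in this block; give up safely
  }
  out <- fgI == 1L
  ## component guard: restore a centre pixel for any fully-deleted component
  kept <- unique(compBefore[out])
  for (k in setdiff(seq_len(max(compBefore)), kept)) {
    pix <- which(compBefore == k, arr.ind = TRUE)
    ctr <- colMeans(pix)
    d2 <- (pix[, 1L] - ctr[1L])^2 + (pix[, 2L] - ctr[2L])^2
    best <- pix[order(d2, pix[, 1L], pix[, 2L])[1L], , drop = FALSE]
    out[best] <- TRUE
  }
  new("BinaryMask", pixels = out, pixelSizeUm = mask@pixelSizeUm,
      threshold = mask@threshold, validMask = mask@validMask)
}

#' Tag and label a 1-px skeleton
#'
#' Assigns per-pixel roles from the 8-neighbour count (0-1 neighbours:
#' endpoint; 2: slab; 3+: junction) and per-object labels from 8-connected
#' components, numbered in raster-scan order of each object's first pixel.
#'
#' @param skeleton a thin [BinaryMask-class] (no 2x2 block entirely
#'   foreground); a non-thin input is a contract violation and errors.
#' @return a [TaggedSkeleton-class]
#' @export
tagAndLabel <- function(skeleton) {
  fg <- skeleton@pixels
  nr <- nrow(fg); nc <- ncol(fg)
  if (nr > 1L && nc > 1L &&
      any(fg[-nr, -nc] & fg[-1L, -nc] & fg[-nr, -1L] & fg[-1L, -1L]))
    stop("contract violation: input skeleton is not thin ",
         "(a 2x2 block is entirely foreground)")
  nb <- neighborCount8(fg)
  tags <- matrix(TAG_BG, nr, nc)
  tags[fg & nb <= 1L] <- TAG_END
  tags[fg & nb == 2L] <- TAG_SLAB
  tags[fg & nb >= 3L] <- TAG_JUNC
  new("TaggedSkeleton", tags = tags, labels = label8(fg),
      pixelSizeUm = skeleton@pixelSizeUm)
}

## Adjacency lists among a set of pixels given by linear indices.
## Returns a list mapping position in `idx` to integer vector of adjacent
## positions (8-connectivity).
pixelAdjacency <- function(idx, nr, nc) {
  n <- length(idx)
  adj <- vector("list", n)
  if (n == 0L) return(adj)
  lut <- integer(nr * nc); lut[idx] <- seq_len(n)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(NEIGH8))) {
    r2 <- r + NEIGH8[k, 1L]; c2 <- c + NEIGH8[k, 2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- lut[j] > 0L
    from <- c(from, which(ok)[hit]); to <- c(to, lut[j][hit])
  }
  if (length(from)) {
    sp <- split(to, from)
    adj[as.integer(names(sp))] <- sp
  }
  adj
}

## raster (row-major) order key of linear (column-major) indices
rasterKey <- function(idx, nr, nc) {
  r <- ((idx - 1L) %% nr); c <- ((idx - 1L) %/% nr)
  r * nc + c
}

#' Build the branch graph of a tagged skeleton
#'
#' 8-adjacent junction pixels merge into single junction nodes (centroid
#' coordinates); branches are traced through slab pixels from node to node,
#' with metric lengths using the orthogonal-1 / diagonal-sqrt(2) step rule.
#' Isolated pixels become degenerate one-node objects with no branches; a
#' closed curve without junctions becomes one object with a single
#' self-edge on an anchor node.
#'
#' Junction-to-junction branches of `mergeGapPx` or fewer path pixels are
#' contracted: thinning a Y- or X-crossing of wide tubes can split one
#' biological junction into two clusters a pixel or two apart, and the
#' contraction restores the single merged junction node.
#'
#' @param tagged a [TaggedSkeleton-class]
#' @param mergeGapPx contract junction-junction branches with at most this
#'   many intermediate path pixels (default 2; 0 disables).
#' @return a [SkeletonGraph-class]
#' @export
buildSkeletonGraph <- function(tagged, mergeGapPx = 2) {
  tg <- tagged@tags; lab <- tagged@labels
  nr <- nrow(tg); nc <- ncol(tg)
  psz <- tagged@pixelSizeUm

  nodes <- data.frame(nodeId = integer(0), objectId = integer(0),
                      type = character(0), row = numeric(0), col = numeric(0),
                      pxRow = integer(0), pxCol = integer(0), nPx = integer(0))
  edges <- data.frame(edgeId = integer(0), objectId = integer(0),
                      fromNode = integer(0), toNode = integer(0),
                      nPathPx = integer(0), lengthUm = numeric(0))
  paths <- list()

  ## --- junction clusters -> nodes
  jclust <- label8(tg == TAG_JUNC)
  nodeOfPixel <- matrix(0L, nr, nc)  # node id carried by junction/endpoint px
  nextNode <- 0L
  nj <- max(jclust)
  for (k in seq_len(nj)) {
    pix <- which(jclust == k, arr.ind = TRUE)
    nextNode <- nextNode + 1L
    nodes[nextNode, ] <- list(nextNode, lab[pix[1L, 1L], pix[1L, 2L]],
                              "junction", mean(pix[, 1L]), mean(pix[, 2L]),
                              pix[1L, 1L], pix[1L, 2L], nrow(pix))
    nodeOfPixel[pix] <- nextNode
  }

  ## --- endpoints -> nodes (raster order)
  eIdx <- which(tg == TAG_END)
  eIdx <- eIdx[order(rasterKey(eIdx, nr, nc))]
  for (i in eIdx) {
    r <- ((i - 1L) %% nr) + 1L; c <- ((i - 1L) %/% nr) + 1L
    nextNode <- nextNode + 1L
    nodes[nextNode, ] <- list(nextNode, lab[r, c], "endpoint",
                              as.numeric(r), as.numeric(c), r, c, 1L)
    nodeOfPixel[r, c] <- nextNode
  }

  ## --- branch segments: skeleton minus junction pixels
  segLab <- label8(tg == TAG_SLAB | tg == TAG_END)
  nSeg <- max(segLab)
  nextEdge <- 0L
  fgJ <- tg == TAG_JUNC

  adjacentJunction <- function(r, c, exclude = NULL) {
    ## junction pixels 8-adjacent to (r, c), as linear indices in raster order
    cand <- integer(0)
    for (k in seq_len(8L)) {
      rr <- r + NEIGH8[k, 1L]; cc <- c + NEIGH8[k, 2L]
      if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc && fgJ[rr, cc])
        cand <- c(cand, (cc - 1L) * nr + rr)
    }
    if (length(exclude)) cand <- setdiff(cand, exclude)
    if (!length(cand)) return(NA_integer_)
    cand[order(rasterKey(cand, nr, nc))][1L]
  }

  ## branches terminate at the merged junction node, so paths attached to a
  ## multi-pixel junction cluster are extended to the cluster centroid
  extendToCentroid <- function(path, nodeId, atHead) {
    if (nodes$type[nodeId] != "junction") return(path)
    ctr <- c(nodes$row[nodeId], nodes$col[nodeId])
    endPt <- if (atHead) path[1L, ] else path[nrow(path), ]
    if (sum((endPt - ctr)^2) < 1e-18) return(path)
    if (atHead) rbind(ctr, path) else rbind(path, ctr)
  }

  addEdge <- function(objectId, fromNode, toNode, path, nDistinct) {
    path <- extendToCentroid(path, fromNode, atHead = TRUE)
    path <- extendToCentroid(path, toNode, atHead = FALSE)
    nextEdge <<- nextEdge + 1L
    edges[nextEdge, ] <<- list(nextEdge, objectId, fromNode, toNode,
                               nDistinct, pathLengthUm(path, psz))
    paths[[nextEdge]] <<- path
  }

  for (s in seq_len(nSeg)) {
    idx <- which(segLab == s)
    idx <- idx[order(rasterKey(idx, nr, nc))]
    n <- length(idx)
    r <- ((idx - 1L) %% nr) + 1L
    c <- ((idx - 1L) %/% nr) + 1L
    objId <- lab[r[1L], c[1L]]
    adj <- pixelAdjacency(idx, nr, nc)
    deg <- lengths(adj)

    if (n == 1L) {
      if (tg[r, c] == TAG_END) {
        jn <- adjacentJunction(r, c)
        if (is.na(jn)) next  # isolated pixel: degenerate node-only object
        jr <- ((jn - 1L) %% nr) + 1L; jc <- ((jn - 1L) %/% nr) + 1L
        addEdge(objId, nodeOfPixel[r, c], nodeOfPixel[jr, jc],
                rbind(c(r, c), c(jr, jc)), 1L)
      } else {
        ## lone slab bridging two junction attachments
        j1 <- adjacentJunction(r, c)
        j2 <- adjacentJunction(r, c, exclude = j1)
        if (is.na(j2)) j2 <- j1  # both neighbours in one pixel: self loop
        j1r <- ((j1 - 1L) %% nr) + 1L; j1c <- ((j1 - 1L) %/% nr) + 1L
        j2r <- ((j2 - 1L) %% nr) + 1L; j2c <- ((j2 - 1L) %/% nr) + 1L
        addEdge(objId, nodeOfPixel[j1r, j1c], nodeOfPixel[j2r, j2c],
                rbind(c(j1r, j1c), c(r, c), c(j2r, j2c)), 1L)
      }
      next
    }

    endsPos <- which(deg <= 1L)
    if (length(endsPos) == 0L) {
      ## pure closed loop: anchor node at raster-first pixel, self-edge
      ord <- integer(n); ord[1L] <- 1L
      prev <- 0L; cur <- 1L
      for (t in 2:n) {
        nbr <- adj[[cur]]
        nxt <- nbr[nbr != prev]
        nxt <- nxt[order(rasterKey(idx[nxt], nr, nc))][1L]
        ord[t] <- nxt; prev <- cur; cur <- nxt
      }
      path <- cbind(r[ord], c[ord])
      path <- rbind(path, path[1L, ])  # closing step
      nextNode <- nextNode + 1L
      nodes[nextNode, ] <- list(nextNode, objId, "anchor",
                                as.numeric(r[1L]), as.numeric(c[1L]),
                                r[1L], c[1L], 1L)
      addEdge(objId, nextNode, nextNode, path, n)
      next
    }

    ## open path: trace from the raster-first end to the other end
    start <- endsPos[1L]
    ord <- integer(n); ord[1L] <- start
    prev <- 0L; cur <- start
    for (t in seq_len(n - 1L)) {
      nbr <- adj[[cur]]
      nxt <- nbr[nbr != prev]
      ord[t + 1L] <- nxt[1L]; prev <- cur; cur <- nxt[1L]
    }
    path <- cbind(r[ord], c[ord])
    nDistinct <- n

    terminalNode <- function(pos, usedJunction = NULL) {
      pr <- r[pos]; pc <- c[pos]
      if (tg[pr, pc] == TAG_END)
        list(node = nodeOfPixel[pr, pc], ext = NULL, jpx = NA_integer_)
      else {
        jn <- adjacentJunction(pr, pc, exclude = usedJunction)
        if (is.na(jn)) jn <- adjacentJunction(pr, pc)
        jr <- ((jn - 1L) %% nr) + 1L; jc <- ((jn - 1L) %/% nr) + 1L
        list(node = nodeOfPixel[jr, jc], ext = c(jr, jc), jpx = jn)
      }
    }
    t1 <- terminalNode(ord[1L])
    t2 <- terminalNode(ord[n], usedJunction =
                         if (n == 1L) t1$jpx else NULL)
    if (!is.null(t1$ext)) path <- rbind(t1$ext, path)
    if (!is.null(t2$ext)) path <- rbind(path, t2$ext)
    addEdge(objId, t1$node, t2$node, path, nDistinct)
  }

  ## contract short junction-junction connectors (split-junction artifact)
  if (mergeGapPx > 0) repeat {
    isJ <- function(id) nodes$type[match(id, nodes$nodeId)] == "junction"
    cand <- which(edges$fromNode != edges$toNode &
                  isJ(edges$fromNode) & isJ(edges$toNode) &
                  edges$nPathPx <= mergeGapPx)
    if (!length(cand)) break
    e <- cand[1L]
    keep <- min(edges$fromNode[e], edges$toNode[e])
    drop <- max(edges$fromNode[e], edges$toNode[e])
    ki <- match(keep, nodes$nodeId); di <- match(drop, nodes$nodeId)
    w <- nodes$nPx[ki] + nodes$nPx[di]
    nodes$row[ki] <- (nodes$row[ki] * nodes$nPx[ki] +
                      nodes$row[di] * nodes$nPx[di]) / w
    nodes$col[ki] <- (nodes$col[ki] * nodes$nPx[ki] +
                      nodes$col[di] * nodes$nPx[di]) / w
    nodes$nPx[ki] <- w
    nodes <- nodes[-di, , drop = FALSE]
    edges$fromNode[edges$fromNode == drop] <- keep
    edges$toNode[edges$toNode == drop] <- keep
    edges <- edges[-e, , drop = FALSE]
    paths[[e]] <- NULL
  }
  edges$edgeId <- seq_len(nrow(edges))
  new("SkeletonGraph", nodes = nodes, edges = edges, paths = paths,
      pixelSizeUm = psz)
}

#' Prune short terminal spurs from a tagged skeleton
#'
#' Removes branches that run from a junction to an endpoint and are shorter
#' than `minSpurPx` pixels. Such spurs are the dominant artifact of
#' thinning a noisy, rough-edged tube mask: each one fabricates a junction
#' that the underlying tubule does not have. Pruning iterates (a pruned
#' junction may expose a new short spur), re-thinning and re-tagging after
#' each pass. Real side branches are unaffected as long as they exceed the
#' threshold.
#'
#' @param tagged a [TaggedSkeleton-class]
#' @param minSpurPx prune junction-to-endpoint branches with fewer than
#'   this many pixels (default 3); 0 disables pruning.
#' @return a [TaggedSkeleton-class]
#' @export
pruneSpurs <- function(tagged, minSpurPx = 3) {
  if (minSpurPx <= 0) return(tagged)
  for (pass in 1:3) {
    g <- buildSkeletonGraph(tagged)
    nd <- g@nodes; ed <- g@edges
    typeOf <- function(id) nd$type[match(id, nd$nodeId)]
    spur <- which((typeOf(ed$fromNode) == "junction" &
                   typeOf(ed$toNode) == "endpoint" |
                   typeOf(ed$fromNode) == "endpoint" &
                   typeOf(ed$toNode) == "junction") &
                  ed$nPathPx < minSpurPx)
    if (!length(spur)) break
    fg <- tagged@tags > TAG_BG
    for (e in spur) {
      p <- g@paths[[e]]
      ## drop only the spur's own pixels: integer path points that are not
      ## junction-tagged (termini include the junction pixel and centroid)
      keepJ <- tagged@tags[cbind(round(p[, 1L]), round(p[, 2L]))] == TAG_JUNC
      whole <- p[, 1L] == round(p[, 1L]) & p[, 2L] == round(p[, 2L])
      drop <- p[whole & !keepJ, , drop = FALSE]
      fg[cbind(drop[, 1L], drop[, 2L])] <- FALSE
    }
    ## re-thin (removes now-redundant junction pixels) and re-tag
    sk <- skeletonize(new("BinaryMask", pixels = fg,
                          pixelSizeUm = tagged@pixelSizeUm))
    tagged <- tagAndLabel(sk)
  }
  tagged
}
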