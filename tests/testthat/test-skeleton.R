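test_that("thinning reduces a ribbon to its centerline and preserves topology", {
  m <- matrix(FALSE, 10, 30); m[4:6, 5:25] <- TRUE
  sk <- pixels(skeletonize(mkMask(m)))
  expect_gte(sum(sk), 18); expect_lte(sum(sk), 21)
  expect_identical(max(MitoNetQuant:::label8(sk)), 1L)

  ## annulus -> single closed loop: 1 object, no endpoints, one self-edge
  g <- buildSkeletonGraph(tagAndLabel(skeletonize(mkMask(annulusMask()))))
  nd <- graphNodes(g); ed <- graphEdges(g)
  expect_identical(length(unique(nd$objectId)), 1L)
  expect_identical(sum(nd$type == "endpoint"), 0L)
  expect_identical(sum(nd$type == "junction"), 0L)
  expect_identical(nrow(ed), 1L)
  expect_identical(ed$fromNode, ed$toNode)
})

test_that("thinning is idempotent on 1-px curves and never drops components", {
  m <- matrix(FALSE, 20, 20); m[10, 3:17] <- TRUE
  expect_identical(pixels(skeletonize(mkMask(m))), m)
  d <- pixels(skeletonize(mkMask(diagonalMask(9))))
  expect_identical(d, diagonalMask(9))
  ## an isolated 2x2 block survives as at least one pixel
  b <- matrix(FALSE, 10, 10); b[3:4, 3:4] <- TRUE
  expect_gte(sum(pixels(skeletonize(mkMask(b)))), 1)
  ## component count preserved on a random blob field
  set.seed(42)
  x <- as.matrix(EBImage::gblur(matrix(runif(64^2), 64, 64), sigma = 2))
  fg <- x > quantile(x, 0.8)
  expect_identical(max(MitoNetQuant:::label8(pixels(skeletonize(mkMask(fg))))),
                   max(MitoNetQuant:::label8(fg)))
})

test_that("tagging matches the brute-force neighbour-count oracle and rejects non-thin input", {
  for (sd in 1:12) {
    fg <- randomThinSkeleton(sd)
    expect_identical(skeletonTags(tagAndLabel(mkMask(fg))), oracleTags(fg))
  }
  thick <- matrix(FALSE, 10, 10); thick[3:6, 3:6] <- TRUE
  expect_error(tagAndLabel(mkMask(thick)), "not thin")
})

test_that("labels number objects in raster-scan order of first pixel", {
  m <- matrix(FALSE, 20, 20)
  m[15, 2:6] <- TRUE    # lower-left object, later in raster order
  m[3, 10:14] <- TRUE   # upper-right object, first in raster order
  lab <- objectLabels(tagAndLabel(mkMask(m)))
  expect_identical(lab[3, 10], 1L)
  expect_identical(lab[15, 2], 2L)
})

test_that("the plus cross yields one 4-armed junction with exact arm lengths", {
  g <- buildSkeletonGraph(tagAndLabel(mkMask(plusCrossMask(), psz = 0.5)))
  nd <- graphNodes(g); ed <- graphEdges(g)
  expect_identical(length(unique(nd$objectId)), 1L)
  expect_identical(sum(nd$type == "junction"), 1L)
  expect_identical(sum(nd$type == "endpoint"), 4L)
  expect_identical(nrow(ed), 4L)
  expect_equal(ed$lengthUm, rep(10 * 0.5, 4))
})

test_that("the H shape yields 2 junctions, 4 endpoints and 5 branches", {
  g <- buildSkeletonGraph(tagAndLabel(mkMask(hShapeMask())))
  nd <- graphNodes(g)
  expect_identical(sum(nd$type == "junction"), 2L)
  expect_identical(sum(nd$type == "endpoint"), 4L)
  expect_identical(nrow(graphEdges(g)), 5L)
})

test_that("a perfect diagonal measures 10 sqrt(2) pixel lengths", {
  g <- buildSkeletonGraph(tagAndLabel(mkMask(diagonalMask(11), psz = 0.2)))
  ed <- graphEdges(g)
  expect_identical(nrow(ed), 1L)
  expect_equal(ed$lengthUm, 10 * sqrt(2) * 0.2)
})

test_that("disjoint segments and isolated pixels are degenerate objects", {
  m <- matrix(FALSE, 20, 30)
  m[5, 3:13] <- TRUE; m[15, 3:13] <- TRUE
  tg <- tagAndLabel(mkMask(m))
  g <- buildSkeletonGraph(tg)
  expect_identical(max(objectLabels(tg)), 2L)
  expect_identical(sum(graphNodes(g)$type == "endpoint"), 4L)
  expect_identical(sum(graphNodes(g)$type == "junction"), 0L)

  iso <- matrix(FALSE, 10, 10); iso[5, 5] <- TRUE
  gi <- buildSkeletonGraph(tagAndLabel(mkMask(iso)))
  expect_identical(nrow(graphNodes(gi)), 1L)
  expect_identical(nrow(graphEdges(gi)), 0L)
})

test_that("graph counts match the independent pixel-graph oracle on random skeletons", {
  for (sd in 1:40) {
    fg <- randomThinSkeleton(sd, 32L)
    g <- buildSkeletonGraph(tagAndLabel(mkMask(fg)))
    nd <- graphNodes(g)
    ora <- oracleGraphCounts(fg)
    expect_identical(sum(nd$type == "junction"), ora$nJunction)
    expect_identical(sum(nd$type == "endpoint"), ora$nEndpoint)
    expect_identical(nrow(graphEdges(g)), ora$nEdges)
  }
})

test_that("branch paths cover every skeleton pixel exactly once", {
  for (sd in c(3, 17)) {
    fg <- randomThinSkeleton(sd)
    tg <- tagAndLabel(mkMask(fg))
    g <- buildSkeletonGraph(tg)
    seen <- matrix(0L, nrow(fg), ncol(fg))
    for (p in branchPaths(g)) {
      whole <- p[, 1] == round(p[, 1]) & p[, 2] == round(p[, 2])
      q <- unique(p[whole, , drop = FALSE])
      seen[q] <- seen[q] + 1L
    }
    nd <- graphNodes(g)
    seen[cbind(nd$pxRow, nd$pxCol)] <- pmax(seen[cbind(nd$pxRow, nd$pxCol)], 1L)
    ## junction-cluster pixels count as node coverage
    seen[skeletonTags(tg) == 3L] <- pmax(seen[skeletonTags(tg) == 3L], 1L)
    expect_true(all(seen[fg] >= 1L))
    expect_true(all(seen[!fg] == 0L))
    ## slab pixels belong to exactly one branch path
    expect_true(all(seen[skeletonTags(tg) == 1L] == 1L))
  }
})

test_that("skeleton counts are invariant under rotation and mirror flips", {
  ## tubular masks, the structures the pipeline quantifies
  for (sd in c(6L, 23L, 31L)) {
    s <- simulateImage(simParams(seed = sd, branchingProb = 0.4,
                                 gaussianNoiseSd = 0, poissonGain = 0,
                                 psfSigmaPx = 0))
    fg <- pixels(s$truthMask)
    counts <- function(m) {
      g <- buildSkeletonGraph(tagAndLabel(skeletonize(mkMask(m))))
      nd <- graphNodes(g)
      list(c(obj = length(unique(nd$objectId)),
             j = sum(nd$type == "junction"),
             e = sum(nd$type == "endpoint")),
           sum(graphEdges(g)$lengthUm))
    }
    base <- counts(fg)
    for (m in list(t(fg[nrow(fg):1, ]),      # 90 degrees clockwise
                   fg[nrow(fg):1, ],         # vertical flip
                   fg[, ncol(fg):1])) {      # horizontal flip
      got <- counts(m)
      expect_identical(got[[1]], base[[1]])
      ## total length agrees up to the thinning algorithm's directional bias
      expect_lt(abs(got[[2]] - base[[2]]) / base[[2]], 0.02)
    }
  }
})

test_that("total branch length is bounded by the pixel count metric", {
  for (sd in c(2, 31)) {
    fg <- randomThinSkeleton(sd)
    g <- buildSkeletonGraph(tagAndLabel(mkMask(fg, psz = 1)))
    total <- sum(graphEdges(g)$lengthUm)
    expect_lte(total, sum(fg) * sqrt(2) + 2 * sqrt(2) * nrow(graphEdges(g)))
    expect_gte(total, 0)
  }
})

test_that("spur pruning removes sub-threshold dead ends but keeps real branches", {
  m <- matrix(FALSE, 20, 40)
  m[10, 3:37] <- TRUE      # long horizontal line
  m[8:9, 20] <- TRUE       # 2-px stub -> spurious junction
  m[3:9, 30] <- TRUE       # 7-px real side branch
  tg <- tagAndLabel(mkMask(m))
  g0 <- buildSkeletonGraph(tg)
  expect_identical(sum(graphNodes(g0)$type == "junction"), 2L)
  gp <- buildSkeletonGraph(pruneSpurs(tg, 3))
  expect_identical(sum(graphNodes(gp)$type == "junction"), 1L)
  expect_identical(nrow(graphEdges(gp)), 3L)
  ## pruning disabled is the identity
  expect_identical(skeletonTags(pruneSpurs(tg, 0)), skeletonTags(tg))
})

test_that("noiseless synthetic networks are recovered exactly", {
  for (sd in c(4L, 9L, 14L)) {
    p <- simParams(nObjects = 8L, branchingProb = 0.5, seed = sd,
                   gaussianNoiseSd = 0, poissonGain = 0, psfSigmaPx = 0)
    s <- simulateImage(p)
    tg <- tagAndLabel(skeletonize(s$truthMask))
    g <- buildSkeletonGraph(tg)
    expect_identical(max(objectLabels(tg)), s$truth$trueObjectCount)
    expect_identical(sum(graphNodes(g)$type == "junction"),
                     s$truth$trueJunctionCount)
  }
})
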