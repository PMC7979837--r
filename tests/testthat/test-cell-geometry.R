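test_that("convex hulls are exact on a unit cube and flag degenerate cells", {
  polys <- buildCellPolygons(cubeSpots())
  expect_equal(length(polys), 1)
  p <- polygonOf(polys, "c1")
  expect_equal(p$volumeUm3, 1.0, tolerance = 1e-12)
  expect_equal(nrow(p$vertices), 8)
  expect_equal(p$centroid, c(0.5, 0.5, 0.5), tolerance = 1e-12)
  expect_equal(p$sourceSpotCount, 8)

  coplanar <- cubeSpots(cellId = "flat")[1:3, ]
  coplanar$z_um <- 0
  both <- rbind(cubeSpots(), coplanar)
  expect_message(polys <- buildCellPolygons(both), "degenerate")
  expect_identical(degenerateCells(polys), "flat")
  expect_identical(cellIds(polys), "c1")

  empty <- buildCellPolygons(cubeSpots()[0, ])
  expect_equal(length(empty), 0)
})

test_that("every source point satisfies the hull half-spaces (1e-9 um)", {
  set.seed(7)
  dirs <- matrix(rnorm(600), 200, 3)
  ball <- dirs / sqrt(rowSums(dirs^2)) * runif(200)^(1 / 3)
  h <- convexHull3d(ball)
  expect_lte(spotcells:::.maxHalfspaceViolation(ball, h), 1e-9)
  # and hull vertices are a subset of the input
  expect_true(all(apply(h$vertices, 1, function(v)
    any(colSums(abs(t(ball) - v)) < 1e-12))))
})

test_that("polygon pair distance matches simple and sampled oracles", {
  a <- convexHull3d(makeCube())
  b <- convexHull3d(makeCube(origin = c(2, 0, 0)))   # faces 1 um apart
  expect_equal(polygonPairDistance(a, b), 1.0, tolerance = 1e-6)
  c <- convexHull3d(makeCube(origin = c(0.5, 0.5, 0.5)))
  expect_equal(polygonPairDistance(a, c), 0)

  set.seed(21)
  for (i in 1:50) {
    ha <- convexHull3d(randomCloud(sample(8:25, 1)))
    hb <- convexHull3d(randomCloud(sample(8:25, 1),
                                   centre = c(runif(1, 2.2, 4), 0, 0)))
    d <- polygonPairDistance(ha, hb)
    sampled <- minPairDistance(sampleHullBoundary(ha, 3000, 0.01),
                               sampleHullBoundary(hb, 3000, 0.01))
    expect_gt(d, 0)
    expect_lt(abs(d - sampled), 1e-3)
  }
})

test_that("contact adjacency follows the 2r Minkowski threshold", {
  mk <- function(gap) {
    rbind(cubeSpots(cellId = "a"),
          cubeSpots(origin = c(1 + gap, 0, 0), cellId = "b"))
  }
  polys <- buildCellPolygons(mk(1.0))
  g <- detectContactNeighbours(polys, expansionUm = 0.6)
  expect_identical(edges(g), spotcells:::.canonicalEdges(rbind(c("a", "b"))))

  polys <- buildCellPolygons(mk(1.5))
  g <- detectContactNeighbours(polys, expansionUm = 0.6)
  expect_equal(nrow(edges(g)), 0)

  # single polygon: one node, no edges
  g1 <- detectContactNeighbours(buildCellPolygons(cubeSpots()), 0.6)
  expect_identical(cellIds(g1), "c1")
  expect_equal(nrow(edges(g1)), 0)
})

test_that("a 19-cell touching hexagonal monolayer gives the centre cell 6 neighbours", {
  emb <- simulateEmbryo(SimParams(nCellsTarget = 19L, membraneJitterUm = 0),
                        seed = 5)
  polys <- buildCellPolygons(membraneSpots(emb))
  g <- detectContactNeighbours(polys, expansionUm = 0.6)
  truth <- trueAdjacency(emb)
  centre <- names(which(neighbourCounts(truth) == 6))
  expect_gt(length(centre), 0)
  for (id in centre)
    expect_identical(neighboursOf(g, id), neighboursOf(truth, id))
})

test_that("radius neighbourhoods match definitions and brute force", {
  cen <- cbind(0:9, 0, 0)
  rownames(cen) <- sprintf("c%02d", 0:9)
  g <- detectRadiusNeighbours(cen, 1.1)
  deg <- neighbourCounts(g)
  expect_equal(unname(deg[c(1, 10)]), c(1L, 1L))
  expect_true(all(deg[2:9] == 2L))

  expect_equal(nrow(edges(detectRadiusNeighbours(cen, 0))), 0)

  # duplicate centroids form a (logged) edge
  dup <- rbind(a = c(0, 0, 0), b = c(0, 0, 0))
  expect_message(gd <- detectRadiusNeighbours(dup, 1), "identical centroids")
  expect_equal(nrow(edges(gd)), 1)

  set.seed(13)
  cen <- matrix(runif(900, 0, 30), 300, 3)
  rownames(cen) <- sprintf("r%03d", 1:300)
  g <- detectRadiusNeighbours(cen, 5)
  expect_identical(unname(edges(g)), unname(bruteRadiusEdges(cen, 5)))
})

test_that("edge sets grow monotonically with their parameter", {
  emb <- simulateEmbryo(smallParams(40L), seed = 2)
  polys <- buildCellPolygons(membraneSpots(emb))
  prev <- character(0)
  for (r in c(0.2, 0.6, 1.0, 2.0)) {
    g <- detectContactNeighbours(polys, r)
    expect_true(all(prev %in% edgeKey(edges(g))))
    prev <- edgeKey(edges(g))
  }
  cen <- centroids(polys)
  prev <- character(0)
  for (R in c(3, 6, 9, 12)) {
    g <- detectRadiusNeighbours(cen, R)
    expect_true(all(prev %in% edgeKey(edges(g))))
    prev <- edgeKey(edges(g))
  }
})

test_that("all produced graphs are symmetric, irreflexive and canonical", {
  emb <- simulateEmbryo(smallParams(30L), seed = 9)
  polys <- buildCellPolygons(membraneSpots(emb))
  for (g in list(detectContactNeighbours(polys, 0.6),
                 detectRadiusNeighbours(centroids(polys), 7),
                 trueAdjacency(emb))) {
    e <- edges(g)
    expect_true(validObject(g))
    if (nrow(e)) {
      expect_true(all(e[, 1] < e[, 2]))       # irreflexive + within-row order
      expect_false(anyDuplicated(e) > 0)      # each unordered pair once
      expect_true(all(e %in% cellIds(g)))
    }
  }
})

test_that("spots are assigned by containment, ties by nearest centroid", {
  polys <- buildCellPolygons(cubeSpots())
  sp <- data.frame(spot_id = c("in", "out"), kind = "mrna", gene = "g",
                   x_um = c(0.5, 11), y_um = c(0.5, 0.5),
                   z_um = c(0.5, 0.5), intensity = NA_real_, cell_id = "",
                   stringsAsFactors = FALSE)
  res <- suppressMessages(assignSpotsToCells(sp, polys))
  expect_equal(res$cell_id, c("c1", ""))
  expect_false(any(res$ambiguous))

  # overlapping cells: spot inside both goes to the nearest centroid
  polys2 <- buildCellPolygons(rbind(
    cubeSpots(cellId = "left", size = 2),
    cubeSpots(origin = c(1.5, 0, 0), size = 2, cellId = "right")))
  sp2 <- sp[1, ]; sp2$x_um <- 1.6; sp2$y_um <- 1; sp2$z_um <- 1
  res2 <- suppressMessages(assignSpotsToCells(sp2, polys2))
  expect_equal(res2$cell_id, "left")   # centroid at 1 vs 2.5
  expect_true(res2$ambiguous)
})

test_that("inset mRNA spots are recovered 100% by assignment (5000+ spots)", {
  emb <- simulateEmbryo(smallParams(80L), seed = 31)
  expect_gte(nrow(mrnaSpots(emb)), 5000)
  polys <- buildCellPolygons(membraneSpots(emb))
  res <- suppressMessages(assignSpotsToCells(mrnaSpots(emb), polys))
  expect_equal(mean(res$cell_id == res$true_cell_id), 1.0)
  expr <- countsFromSpots(res, centroids(polys))
  truth <- countsMatrix(trueCounts(emb))
  expect_equal(unname(countsMatrix(expr)[rownames(truth), colnames(truth)]),
               unname(truth))
})

test_that("neighbour-count histograms tabulate degrees over all cells", {
  tri <- NeighbourGraph(c("a", "b", "c"),
                        rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  expect_identical(neighbourCountHistogram(tri), c("2" = 3L))
  iso <- NeighbourGraph("lonely")
  expect_identical(neighbourCountHistogram(iso), c("0" = 1L))
  emb <- simulateEmbryo(smallParams(50L), seed = 4)
  h <- neighbourCountHistogram(trueAdjacency(emb))
  expect_equal(sum(h), 50)
})
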