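test_that("the lattice has hexagonal ground-truth adjacency", {
  lat <- generateLattice(SimParams(nCellsTarget = 19L))
  expect_equal(nrow(lat$cells), 19)
  deg <- neighbourCounts(lat$adjacency)
  expect_true(any(deg == 6))                     # interior cells
  expect_true(all(deg >= 2 & deg <= 6))
  expect_error(SimParams(nCellsTarget = 5L), "at least 7")

  big <- generateLattice(SimParams(nCellsTarget = 400L))
  degB <- neighbourCounts(big$adjacency)
  interior <- degB == 6
  expect_gt(mean(interior), 0.5)

  ell <- generateLattice(SimParams(nCellsTarget = 400L, mask = "ellipse"))
  degE <- neighbourCounts(ell$adjacency)
  expect_true(all(degE >= 1 & degE <= 6))
  # an ellipse keeps corner-free boundary: fewer max-degree cells than area
  expect_lt(mean(degE == 6), 1)
})

test_that("footprints tile: neighbouring hexagons share edges, prisms do not overlap", {
  lat <- generateLattice(SimParams(nCellsTarget = 40L))
  cells <- lat$cells
  e <- edges(lat$adjacency)
  idx <- setNames(seq_len(nrow(cells)), cells$cell_id)
  for (k in sample(nrow(e), 10)) {
    ha <- cells$footprint[[idx[e[k, 1]]]]
    hb <- cells$footprint[[idx[e[k, 2]]]]
    shared <- 0
    for (i in 1:6) for (j in 1:6)
      if (sum((ha[i, ] - hb[j, ])^2) < 1e-16) shared <- shared + 1
    expect_equal(shared, 2)   # exactly one shared edge (two vertices)
  }
})

test_that("expression profiles behave per family", {
  u <- patternSpec("u", "uniform", peakMeanCount = 12)
  expect_equal(expressionProfile(u, c(0, 0.3, 1)), rep(12, 3))
  off <- patternSpec("o", "off")
  expect_equal(expressionProfile(off, c(0, 0.5, 1)), rep(0, 3))
  s7 <- patternSpec("e", "stripes", peakMeanCount = 60)
  centres <- seq(0.15, 0.92, length.out = 7)
  mids <- (centres[-1] + centres[-7]) / 2
  expect_gt(min(expressionProfile(s7, centres)),
            10 * max(expressionProfile(s7, mids)))
  bd <- patternSpec("k", "broad_domain", centre = 0.5, width = 0.2,
                    peakMeanCount = 80)
  expect_gt(expressionProfile(bd, 0.5), 0.95 * 80)  # logistic-edged plateau
  expect_lt(expressionProfile(bd, 0.9), 1)
  gr <- patternSpec("g", "gradient", peakMeanCount = 50)
  prof <- expressionProfile(gr, seq(0, 1, 0.1))
  expect_true(all(diff(prof) < 0))
})

test_that("count sampling follows the configured noise law", {
  cells <- data.frame(cell_id = sprintf("c%05d", 1:20000), ap = 0.5,
                      x_um = 0, y_um = 0, z_basal_um = 0, z_apical_um = 9.6)
  spec <- list(patternSpec("u", "uniform", peakMeanCount = 20))
  pois <- countsMatrix(sampleCounts(cells, spec, "poisson", seed = 1))[, 1]
  expect_equal(mean(pois), 20, tolerance = 0.5 / sqrt(2))
  expect_equal(fanoFactor(pois), 1, tolerance = 0.05)
  nb <- countsMatrix(sampleCounts(cells, spec, "negative_binomial",
                                  seed = 2, nbFano = 3))[, 1]
  expect_equal(fanoFactor(nb), 3, tolerance = 0.2)
  offg <- list(patternSpec("o", "off"))
  expect_true(all(countsMatrix(sampleCounts(cells, offg, seed = 3)) == 0))
})

test_that("spot generation conserves counts and respects geometry", {
  prm <- smallParams(40L, membraneJitterUm = 0)
  emb <- simulateEmbryo(prm, seed = 6)
  mem <- membraneSpots(emb)
  expect_equal(nrow(mem), 40 * prm$membraneSpotsPerCell)
  expect_equal(nrow(mrnaSpots(emb)), sum(countsMatrix(trueCounts(emb))))

  # jitter 0: every membrane spot on its prism boundary (face, rim or edge)
  cells <- emb@cells
  idx <- setNames(seq_len(nrow(cells)), cells$cell_id)
  apothem <- prm$cellDiameterUm / 2
  onBoundary <- vapply(seq_len(nrow(mem)), function(i) {
    ci <- idx[mem$cell_id[i]]
    dz <- min(mem$z_um[i], prm$depthUm - mem$z_um[i])
    dxy <- apothem - max(abs(
      cbind(mem$x_um[i] - cells$x_um[ci], mem$y_um[i] - cells$y_um[ci]) %*%
        t(cbind(cos((0:5) * pi / 3), sin((0:5) * pi / 3)))))
    min(abs(dz), abs(dxy)) < 1e-9 && dz > -1e-9 && dxy > -1e-9
  }, logical(1))
  expect_true(all(onBoundary))

  # jitter-0 hulls recover the prism volume within 15%
  polys <- buildCellPolygons(mem)
  prism <- 3 * sqrt(3) / 2 * (prm$cellDiameterUm / sqrt(3))^2 * prm$depthUm
  expect_true(all(abs(volumes(polys) - prism) / prism < 0.15))

  # mRNA spots lie strictly inside their generating prism
  rna <- mrnaSpots(emb)
  ok <- vapply(seq_len(nrow(rna)), function(i) {
    ci <- idx[rna$true_cell_id[i]]
    d <- cbind(rna$x_um[i] - cells$x_um[ci], rna$y_um[i] - cells$y_um[ci])
    all(d %*% t(cbind(cos((0:5) * pi / 3), sin((0:5) * pi / 3))) < apothem) &&
      rna$z_um[i] > 0 && rna$z_um[i] < prm$depthUm
  }, logical(1))
  expect_true(all(ok))
})

test_that("simulation is reproducible under a fixed seed", {
  a <- simulateEmbryo(smallParams(30L), seed = 42)
  b <- simulateEmbryo(smallParams(30L), seed = 42)
  expect_equal(membraneSpots(a), membraneSpots(b))
  expect_equal(mrnaSpots(a), mrnaSpots(b))
  expect_equal(countsMatrix(trueCounts(a)), countsMatrix(trueCounts(b)))
  c <- simulateEmbryo(smallParams(30L), seed = 43)
  expect_false(isTRUE(all.equal(membraneSpots(a)$x_um,
                                membraneSpots(c)$x_um)))
})

test_that("two-channel thinning halves counts on average per channel", {
  cm <- matrix(c(100L, 400L, 0L, 40L), 4, 1,
               dimnames = list(paste0("c", 1:4), "Kr"))
  expr <- CellExpression(cm, matrix(0, 4, 3,
                                    dimnames = list(paste0("c", 1:4), NULL)))
  ch <- twoChannelCounts(expr, "Kr", p = 0.5, seed = 1)
  expect_true(all(ch <= c(cm)))
  expect_equal(ch[3, ], c(channel_a = 0L, channel_b = 0L))
  set.seed(1)
  big <- twoChannelCounts(
    CellExpression(matrix(rep(1000L, 500), 500, 1,
                          dimnames = list(sprintf("c%03d", 1:500), "g")),
                   matrix(0, 500, 3)), "g", seed = 5)
  expect_equal(mean(big[, 1]) / 1000, 0.5, tolerance = 0.01)
})
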