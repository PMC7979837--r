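test_that("Fano factor is the population variance over the mean", {
  expect_equal(fanoFactor(rep(5, 7)), 0)
  expect_equal(fanoFactor(c(0, 0, 4)), 8 / 3)      # var 32/9, mean 4/3
  expect_equal(fanoFactor(c(0, 0, 0)), 0)          # mean-0 convention
  expect_equal(fanoFactor(c(0, 0, 4), sample = TRUE), (16 / 3) / (4 / 3))
  expect_error(fanoFactor(c(-1, 2)), "nonnegative")
  expect_error(fanoFactor(c(1.5, 2)), "nonnegative integers")
  set.seed(1)
  x <- sample(0:50, 8)
  expect_equal(fanoFactor(x), fanoFactor(rev(x)))  # permutation invariance
})

test_that("pooled Fano approaches the law's variance/mean ratio", {
  set.seed(99)
  expect_equal(fanoFactor(rpois(1e5, 20)), 1, tolerance = 0.02)
})

test_that("NV divides the mean neighbour difference by the population max", {
  expect_equal(numericalVariability(1, rep(0, 6), 550), 1 / 550)
  expect_equal(numericalVariability(7, c(7, 7, 7), 550), 0)
  expect_equal(numericalVariability(20, rep(0, 4), 20), 1)
  expect_equal(numericalVariability(3, c(1, 5), 0 + max(3, 1, 5)),
               2 / 5)
  expect_warning(v <- numericalVariability(3, integer(0), 10), "isolated")
  expect_equal(v, 0)
  expect_error(numericalVariability(5, c(0, 1), 3), "populationMax")
})

test_that("PV divides by the neighbour-group max, focal cell included", {
  expect_equal(proportionalVariability(1, rep(0, 6)), 1)
  expect_equal(proportionalVariability(42, rep(42, 4)), 0)
  expect_equal(proportionalVariability(10, rep(5, 4)), 0.5)
  expect_equal(proportionalVariability(0, rep(0, 5)), 0)  # all-zero group
  expect_warning(v <- proportionalVariability(3, integer(0)), "isolated")
  expect_equal(v, 0)
})

test_that("NV and PV stay in [0, 1] and attain both bounds", {
  # exhaustive over neighbour pairs/triples, focal 0..8, values 0..8
  vals <- 0:8
  seen <- c(1, 0)
  for (x in vals) {
    for (i in vals) for (j in vals) {
      for (nb in list(c(i, j), c(i, j, 3))) {
        popMax <- max(x, nb, 1)
        nv <- numericalVariability(x, nb, popMax)
        pv <- proportionalVariability(x, nb)
        expect_true(nv >= 0 && nv <= 1 && pv >= 0 && pv <= 1)
        seen <- range(seen, nv, pv)
      }
    }
  }
  expect_equal(seen, c(0, 1))
  # randomized larger groups
  set.seed(8)
  for (k in 1:2000) {
    nb <- sample(0:20, sample(4:8, 1), replace = TRUE)
    x <- sample(0:20, 1)
    nv <- numericalVariability(x, nb, 20)
    pv <- proportionalVariability(x, nb)
    expect_true(nv >= 0 && nv <= 1 && pv >= 0 && pv <= 1)
  }
})

test_that("NV is shift-invariant; PV falls as the baseline rises", {
  x <- 60; nb <- rep(10, 6); popMax <- 550
  nv0 <- numericalVariability(x, nb, popMax)
  pv0 <- proportionalVariability(x, nb)
  for (shift in c(5, 100, 400)) {
    expect_equal(numericalVariability(x + shift, nb + shift, popMax), nv0)
    expect_lt(proportionalVariability(x + shift, nb + shift), pv0)
  }
  # equal-difference scenarios score the same on both measures
  expect_equal(proportionalVariability(66, rep(11, 6)),
               proportionalVariability(60, rep(10, 6)))
  # focal equal to all but one neighbour: both measures low
  nvD <- numericalVariability(10, c(rep(10, 5), 60), popMax)
  pvD <- proportionalVariability(10, c(rep(10, 5), 60))
  expect_lt(nvD, nv0)
  expect_lt(pvD, pv0)
})

test_that("the PV expression filter zeroes low-expression groups inclusively", {
  expect_equal(applyPvFilter(1, c(1, rep(0, 6))), 0)      # mean 1/7 < 1
  expect_equal(applyPvFilter(0.7, rep(1, 7)), 0.7)        # mean exactly 1
  expect_equal(applyPvFilter(0.3, c(40, 35, 36.6)), 0.3)
  expect_equal(applyPvFilter(0.5, c(0, 1), threshold = 2), 0)
})

test_that("scoreEmbryo reproduces the per-cell formulas and flags", {
  cm <- matrix(c(0L, 10L, 0L), 3, 1,
               dimnames = list(c("a", "b", "c"), "eve"))
  cents <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), NULL))
  expr <- CellExpression(cm, cents)
  chain <- NeighbourGraph(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  sc <- scoreEmbryo(expr, chain)
  b <- sc[sc$cell_id == "b", ]
  expect_equal(b$nv, 1)                     # 10/popmax 10
  expect_equal(b$pv_raw, 1)
  expect_equal(b$fano, fanoFactor(c(10, 0, 0)))
  expect_equal(b$pv_filtered, 1)            # group mean 10/3 >= 1
  a <- sc[sc$cell_id == "a", ]
  expect_equal(a$pv_raw, 1)                 # 0 vs neighbour 10
  expect_equal(a$pv_filtered, 1)            # group mean 5 >= 1

  # all-zero gene scores 0 everywhere
  cm0 <- cm; cm0[] <- 0L
  sc0 <- scoreEmbryo(CellExpression(cm0, cents), chain)
  expect_true(all(sc0[c("fano", "nv", "pv_raw", "pv_filtered")] == 0))

  # isolated cells are flagged and scored 0
  iso <- NeighbourGraph(c("a", "b", "c"), rbind(c("a", "b")))
  sci <- scoreEmbryo(expr, iso)
  expect_true(sci$isolated[sci$cell_id == "c"])
  expect_true(all(sci[sci$cell_id == "c", c("fano", "nv", "pv_raw")] == 0))

  # graph cells must exist in the table
  bad <- NeighbourGraph(c("a", "zz"), rbind(c("a", "zz")))
  expect_error(scoreEmbryo(expr, bad), "zz")

  # deterministic and independent of cell order
  perm <- c("c", "a", "b")
  sc2 <- scoreEmbryo(CellExpression(cm[perm, , drop = FALSE],
                                    cents[perm, ]), chain)
  m1 <- sc[order(sc$cell_id), ]; m2 <- sc2[order(sc2$cell_id), ]
  rownames(m1) <- rownames(m2) <- NULL
  expect_equal(m1, m2)
})

test_that("Fano picks out stripe edges over stripe centres", {
  emb <- simulateEmbryo(smallParams(800L), seed = 17)
  sc <- scoreEmbryo(trueCounts(emb), trueAdjacency(emb))
  sc <- sc[sc$gene == "eve", ]
  fano <- setNames(sc$fano, sc$cell_id)
  ap <- setNames(emb@cells$ap, emb@cells$cell_id)[names(fano)]
  centres <- seq(0.15, 0.92, length.out = 7)
  dist <- vapply(ap, function(a) min(abs(a - centres)), numeric(1))
  centreCells <- dist < 0.01
  edgeCells <- dist > 0.02 & dist < 0.045
  expect_gt(sum(centreCells), 10)
  expect_gt(sum(edgeCells), 10)
  expect_gt(mean(fano[edgeCells]), mean(fano[centreCells]))
})

test_that("count histograms bin by fives with zero excluded", {
  expect_identical(countHistogram(c(0, 1, 5, 6)),
                   c("1-5" = 2L, "6-10" = 1L))
  expect_length(countHistogram(integer(0)), 0)
  expect_length(countHistogram(c(0, 0, 0)), 0)
  expect_identical(countHistogram(c(0, 2), excludeZero = FALSE),
                   c("0" = 1L, "1-5" = 1L))
  expect_identical(names(countHistogram(c(3, 12))),
                   c("1-5", "6-10", "11-15"))   # empty bins kept in order
  expect_error(countHistogram(c(-1, 3)), "nonnegative")
  set.seed(3)
  v <- rpois(1e4, 8)
  expect_equal(sum(countHistogram(v)), sum(v > 0))  # conservation
})

test_that("nascent ratios scale site intensity by the single-spot reference", {
  expect_equal(nascentRatio(100, 10), 10)
  expect_equal(nascentRatio(0, 10), 0)
  expect_error(nascentRatio(5, 0), "positive")
  set.seed(12)
  singles <- rlnorm(500, 2, 0.3)
  k <- 7
  site <- sum(sample(singles, k))
  expect_equal(nascentRatio(site, mean(singles)), k, tolerance = 0.25)
})

test_that("channel concordance is Spearman's rank correlation", {
  expect_equal(channelConcordance(c(1, 2, 3, 5), c(1, 2, 3, 5)), 1)
  expect_equal(channelConcordance(c(1, 2, 3, 5), c(9, 7, 4, 2)), -1)
  expect_warning(r <- channelConcordance(c(2, 2, 2), c(1, 2, 3)),
                 "constant")
  expect_true(is.na(r))
  expect_error(channelConcordance(1:5, 1:4), "equal length")

  emb <- simulateEmbryo(smallParams(400L), seed = 23)
  ch <- twoChannelCounts(trueCounts(emb), "Kr", p = 0.5, seed = 2)
  expect_gt(channelConcordance(ch[, 1], ch[, 2]), 0.9)
})
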