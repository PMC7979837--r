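# Geometry fixtures and independent oracles.

# axis-aligned cube vertices
makeCube <- function(origin = c(0, 0, 0), size = 1) {
  sweep(as.matrix(expand.grid(0:1, 0:1, 0:1)) * size, 2, origin, "+")
}

cubeSpots <- function(origin = c(0, 0, 0), size = 1, cellId = "c1") {
  v <- makeCube(origin, size)
  data.frame(spot_id = paste0(cellId, "_", seq_len(nrow(v))),
             kind = "membrane", gene = "", x_um = v[, 1], y_um = v[, 2],
             z_um = v[, 3], intensity = NA_real_, cell_id = cellId,
             stringsAsFactors = FALSE)
}

# random convex point cloud of unit-ish scale around a centre
randomCloud <- function(n = 20, centre = c(0, 0, 0), scale = 1) {
  sweep(matrix(stats::rnorm(n * 3, sd = scale / 2), n, 3), 2, centre, "+")
}

# points on the hull boundary: all vertices, dense edge samples, and
# area-weighted uniform samples on the triangle faces
sampleHullBoundary <- function(hull, nFace = 2000, edgeStep = 0.02) {
  v <- hull$vertices
  f <- hull$faces
  pts <- v
  edges <- unique(t(apply(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]), 1, sort)))
  for (i in seq_len(nrow(edges))) {
    a <- v[edges[i, 1], ]; b <- v[edges[i, 2], ]
    len <- sqrt(sum((b - a)^2))
    k <- max(2, ceiling(len / edgeStep))
    t <- seq(0, 1, length.out = k)
    pts <- rbind(pts, outer(1 - t, a) + outer(t, b))
  }
  areas <- apply(f, 1, function(tr) {
    ab <- v[tr[2], ] - v[tr[1], ]; ac <- v[tr[3], ] - v[tr[1], ]
    cr <- c(ab[2] * ac[3] - ab[3] * ac[2], ab[3] * ac[1] - ab[1] * ac[3],
            ab[1] * ac[2] - ab[2] * ac[1])
    sqrt(sum(cr^2)) / 2
  })
  tri <- sample(nrow(f), nFace, replace = TRUE, prob = areas)
  r1 <- sqrt(stats::runif(nFace)); r2 <- stats::runif(nFace)
  a <- v[f[tri, 1], , drop = FALSE]
  b <- v[f[tri, 2], , drop = FALSE]
  c3 <- v[f[tri, 3], , drop = FALSE]
  rbind(pts, (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * c3)
}

minPairDistance <- function(pa, pb) {
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
  sqrt(max(0, min(d2)))
}

# Certificate bounds for "expanded hulls (Minkowski ball radius r)
# intersect". Certificates are verified by direct arithmetic, so they are
# sound regardless of how the candidate points/directions were obtained:
#  - upper bound m: min distance over sampled boundary points (membership
#    checked for candidates taken from elsewhere); m < 2r proves the
#    expanded hulls intersect;
#  - lower bound G: max over unit directions u of the support gap
#    min_A u.a - max_B u.b over the hull vertices; G >= 2r proves the
#    expanded hulls are disjoint.
hullPairBounds <- function(ha, hb, nDirs = 400) {
  inA <- function(p) all(ha$normals %*% p <= ha$offsets + 1e-9)
  inB <- function(p) all(hb$normals %*% p <= hb$offsets + 1e-9)
  ba <- sampleHullBoundary(ha)
  bb <- sampleHullBoundary(hb)
  qp <- convexBodyDistance(ha$vertices, hb$vertices)
  if (inA(qp$pA) && inB(qp$pB))
    { ba <- rbind(ba, qp$pA); bb <- rbind(bb, qp$pB) }
  m <- minPairDistance(ba, bb)
  supGap <- function(u) min(ha$vertices %*% u) - max(hb$vertices %*% u)
  dirs <- matrix(stats::rnorm(nDirs * 3), nDirs, 3)
  gap <- qp$pA - qp$pB
  if (sum(gap^2) > 0) dirs <- rbind(dirs, gap)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  G <- max(apply(dirs, 1, supGap))
  list(m = m, G = G)
}

minkowskiIntersectOracle <- function(ha, hb, r, nDirs = 400) {
  b <- hullPairBounds(ha, hb, nDirs)
  if (b$m < 2 * r) "intersect"
  else if (b$G >= 2 * r) "disjoint"
  else "unknown"
}

# O(n^2) brute-force radius neighbourhood
bruteRadiusEdges <- function(cen, R) {
  ids <- rownames(cen)
  out <- NULL
  for (i in seq_len(nrow(cen) - 1)) {
    for (j in (i + 1):nrow(cen)) {
      if (sqrt(sum((cen[i, ] - cen[j, ])^2)) <= R)
        out <- rbind(out, sort(c(ids[i], ids[j])))
    }
  }
  if (is.null(out)) out <- matrix(character(0), 0, 2)
  colnames(out) <- c("cell_a", "cell_b")
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

edgeKey <- function(e) paste(e[, 1], e[, 2])
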