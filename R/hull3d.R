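## 3D convex-hull primitives.
##
## An incremental hull (quickhull-style visibility/horizon updates) over
## double-precision micrometre coordinates, plus the minimum distance between
## two convex bodies posed as a small quadratic program over convex
## combinations of their vertices. Coordinates are physical micrometres; the
## containment/coplanarity tolerance is 1e-9 um throughout.

.HULL_TOL <- 1e-9

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## initial non-degenerate tetrahedron, or NULL
.initialSimplex <- function(pts, tol) {
  n <- nrow(pts)
  cand <- unique(as.vector(apply(pts, 2, function(v) c(which.min(v), which.max(v)))))
  ## two most distant candidate extremes
  best <- c(NA, NA); bd <- -1
  for (i in cand) {
    d2 <- rowSums(sweep(pts[cand, , drop = FALSE], 2, pts[i, ])^2)
    j <- cand[which.max(d2)]
    if (max(d2) > bd) { bd <- max(d2); best <- c(i, j) }
  }
  if (bd <= tol^2) return(NULL)
  i1 <- best[1]; i2 <- best[2]
  dir <- pts[i2, ] - pts[i1, ]
  ## furthest from the line i1-i2
  rel <- sweep(pts, 2, pts[i1, ])
  proj <- as.vector(rel %*% dir) / sum(dir^2)
  perp2 <- rowSums((rel - outer(proj, dir))^2)
  i3 <- which.max(perp2)
  if (perp2[i3] <= tol^2) return(NULL)
  nrm <- .cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  nrm <- nrm / sqrt(sum(nrm^2))
  h <- as.vector(rel %*% nrm)
  i4 <- which.max(abs(h))
  if (abs(h[i4]) <= tol) return(NULL)
  c(i1, i2, i3, i4)
}

#' Convex hull of a 3D point cloud
#'
#' Incremental convex hull. Returns `NULL` for degenerate input (fewer than
#' four non-coplanar points within tolerance), otherwise a polygon list with
#' triangle faces, outward face half-spaces, solid centroid and volume.
#'
#' @param pts numeric matrix (n x 3) of coordinates in micrometres.
#' @param tol coplanarity/containment tolerance in micrometres.
#' @return `NULL`, or a list with `vertices` (m x 3 matrix of hull vertex
#'   coordinates), `faces` (f x 3 indices into `vertices`, outward
#'   counter-clockwise), `normals` (f x 3 outward unit normals), `offsets`
#'   (length f; a point x is inside iff `normals %*% x <= offsets + tol`),
#'   `centroid`, `volumeUm3` and `nInput`.
#' @examples
#' cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
#' h <- convexHull3d(cube)
#' h$volumeUm3   # 1
#' @export
convexHull3d <- function(pts, tol = .HULL_TOL) {
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3) stop("pts must be an n x 3 matrix")
  if (any(!is.finite(pts))) stop("coordinates must be finite")
  pts <- unique(pts)
  if (nrow(pts) < 4) return(NULL)
  init <- .initialSimplex(pts, tol)
  if (is.null(init)) return(NULL)
  ref <- colMeans(pts[init, ])

  faces <- list()  # each: list(v = int[3], n = num[3], off = num)
  .mkFace <- function(i, j, k) {
    a <- pts[i, ]; b <- pts[j, ]; c <- pts[k, ]
    nrm <- .cross3(b - a, c - a)
    nn <- sqrt(sum(nrm^2))
    if (nn < 1e-14) return(NULL)     # degenerate sliver; caller decides
    nrm <- nrm / nn
    v <- c(i, j, k)
    if (sum(nrm * (ref - a)) > 0) {  # orient outward (ref is interior)
      nrm <- -nrm
      v <- c(i, k, j)
    }
    list(v = v, n = nrm, off = sum(nrm * a))
  }
  combs <- list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  for (cmb in combs) {
    f <- .mkFace(init[cmb[1]], init[cmb[2]], init[cmb[3]])
    if (is.null(f)) return(NULL)
    faces[[length(faces) + 1]] <- f
  }

  rest <- setdiff(seq_len(nrow(pts)), init)
  ## farthest-first insertion reduces degenerate horizons
  if (length(rest) > 1) {
    d2 <- rowSums(sweep(pts[rest, , drop = FALSE], 2, ref)^2)
    rest <- rest[order(-d2)]
  }
  for (p in rest) {
    x <- pts[p, ]
    vis <- which(vapply(faces, function(f) sum(f$n * x) - f$off > tol,
                        logical(1)))
    if (!length(vis)) next
    ## horizon: directed edges of visible faces whose reverse is not visible
    dirEdges <- do.call(rbind, lapply(faces[vis], function(f)
      rbind(f$v[c(1, 2)], f$v[c(2, 3)], f$v[c(3, 1)])))
    keys <- paste(dirEdges[, 1], dirEdges[, 2])
    revKeys <- paste(dirEdges[, 2], dirEdges[, 1])
    horizon <- dirEdges[!(keys %in% revKeys), , drop = FALSE]
    newFaces <- vector("list", nrow(horizon))
    ok <- TRUE
    for (h in seq_len(nrow(horizon))) {
      f <- .mkFace(horizon[h, 1], horizon[h, 2], p)
      if (is.null(f)) { ok <- FALSE; break }
      newFaces[[h]] <- f
    }
    if (!ok) next  # point (near-)on an edge line; it adds no volume > tol
    faces <- c(faces[-vis], newFaces)
  }

  fv <- do.call(rbind, lapply(faces, `[[`, "v"))
  normals <- do.call(rbind, lapply(faces, `[[`, "n"))
  offsets <- vapply(faces, `[[`, numeric(1), "off")
  vid <- sort(unique(as.vector(fv)))
  remap <- integer(nrow(pts)); remap[vid] <- seq_along(vid)
  verts <- pts[vid, , drop = FALSE]
  fv <- matrix(remap[fv], ncol = 3)

  ## solid volume and centroid from signed tetrahedra about ref
  vol <- 0; cen <- c(0, 0, 0)
  for (i in seq_len(nrow(fv))) {
    a <- verts[fv[i, 1], ] - ref
    b <- verts[fv[i, 2], ] - ref
    c3 <- verts[fv[i, 3], ] - ref
    v6 <- sum(a * .cross3(b, c3))
    vol <- vol + v6
    cen <- cen + v6 * (a + b + c3) / 4
  }
  volume <- vol / 6
  centroid <- unname(ref + if (volume > 0) cen / vol else c(0, 0, 0))
  if (volume <= tol) return(NULL)
  rownames(verts) <- NULL
  list(vertices = verts, faces = fv, normals = normals, offsets = offsets,
       centroid = centroid, volumeUm3 = volume, nInput = nrow(pts))
}

## logical vector: which points satisfy all outward half-spaces
.pointsInHull <- function(pts, hull, tol = .HULL_TOL) {
  pts <- as.matrix(pts)
  s <- pts %*% t(hull$normals)                 # n x f
  colSums(t(s) > hull$offsets + tol) == 0
}

## max distance of any point outside the hull's half-spaces (<= 0 if all in)
.maxHalfspaceViolation <- function(pts, hull) {
  s <- as.matrix(pts) %*% t(hull$normals)
  max(sweep(s, 2, hull$offsets))
}

#' Minimum distance between two convex bodies
#'
#' Distance between the convex hulls of two vertex sets, found by minimising
#' `||p - q||` over convex combinations p, q of the respective vertices
#' (a strictly convex QP after a tiny ridge; solved with quadprog). Returns 0
#' (up to numerical precision) exactly when the bodies intersect.
#'
#' @param va,vb numeric matrices (vertices x 3) of the two bodies, in
#'   micrometres. [CellPolygonSet-class] polygons pass their `vertices`.
#' @return list with `distance` (um), and the closest points `pA`, `pB`.
#' @export
convexBodyDistance <- function(va, vb) {
  va <- as.matrix(va); vb <- as.matrix(vb)
  n <- nrow(va); m <- nrow(vb)
  Z <- rbind(va, -vb)
  D <- tcrossprod(Z)
  ridge <- 1e-9 * max(1, max(diag(D)))
  diag(D) <- diag(D) + ridge
  Amat <- cbind(c(rep(1, n), rep(0, m)), c(rep(0, n), rep(1, m)),
                diag(n + m))
  bvec <- c(1, 1, rep(0, n + m))
  sol <- quadprog::solve.QP(D, rep(0, n + m), Amat, bvec, meq = 2)
  w <- sol$solution
  pA <- as.vector(t(va) %*% w[seq_len(n)])
  pB <- as.vector(t(vb) %*% w[n + seq_len(m)])
  d <- sqrt(sum((pA - pB)^2))
  if (d < 1e-7) d <- 0
  list(distance = d, pA = pA, pB = pB)
}
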