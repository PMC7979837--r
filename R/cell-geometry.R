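## Cell geometry: per-cell polygons, neighbour detection, spot assignment.
##
## A cell polygon is the convex hull of its membrane spots. Contact
## neighbours follow the expand-and-intersect idea: each polygon grown in 3D
## by r micrometres (default 0.6, about 10% of a blastoderm cell diameter)
## intersects exactly its immediate neighbours. The expansion is a Minkowski
## sum with a ball of radius r, so two expanded polygons intersect iff the
## original convex bodies are closer than 2r - evaluated exactly via
## convexBodyDistance() rather than by displacing mesh vertices. Ties at
## exactly 2r count as non-adjacent (strict <).

#' Build per-cell 3D polygons from membrane spots
#'
#' Groups membrane spots by their `cell_id` and takes the convex hull of
#' each group. Cells with fewer than four non-coplanar spots cannot span a
#' 3D body and are reported as degenerate instead of being fabricated.
#'
#' @param membraneSpots spot data.frame (schema of [readSpotTable()]); every
#'   spot must carry a non-empty `cell_id`.
#' @param tol geometric tolerance in micrometres.
#' @return a [CellPolygonSet-class]; degenerate cells are listed in
#'   [degenerateCells()] and messaged.
#' @examples
#' cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
#' spots <- data.frame(spot_id = paste0("s", 1:8), kind = "membrane",
#'                     gene = "", x_um = cube[, 1], y_um = cube[, 2],
#'                     z_um = cube[, 3], intensity = NA, cell_id = "c1")
#' polys <- buildCellPolygons(spots)
#' volumes(polys)
#' @export
buildCellPolygons <- function(membraneSpots, tol = 1e-9) {
  if (nrow(membraneSpots) == 0)
    return(new("CellPolygonSet", polygons = list(),
               degenerate = character(0)))
  if (any(membraneSpots$cell_id == "" | is.na(membraneSpots$cell_id)))
    stop("all membrane spots must be assigned to a cell")
  coords <- split.data.frame(
    as.matrix(membraneSpots[, c("x_um", "y_um", "z_um")]),
    membraneSpots$cell_id)
  polys <- list()
  degen <- character(0)
  for (id in names(coords)) {
    h <- convexHull3d(coords[[id]], tol = tol)
    if (is.null(h)) {
      degen <- c(degen, id)
    } else {
      h$cellId <- id
      h$sourceSpotCount <- nrow(coords[[id]])
      polys[[id]] <- h
    }
  }
  if (length(degen))
    message(length(degen), " degenerate cell(s) excluded from geometry: ",
            paste(utils::head(degen, 10), collapse = ", "))
  new("CellPolygonSet", polygons = polys, degenerate = degen)
}

#' Minimum distance between two cell polygons
#'
#' Euclidean distance between the two convex bodies in micrometres; 0 iff
#' they intersect.
#'
#' @param a,b polygon lists (see [polygonOf()]).
#' @return nonnegative distance in micrometres.
#' @export
polygonPairDistance <- function(a, b) {
  convexBodyDistance(a$vertices, b$vertices)$distance
}

## circumradius about the centroid, used for conservative candidate pruning
.circumradius <- function(p)
  sqrt(max(rowSums(sweep(p$vertices, 2, p$centroid)^2)))

.bboxes <- function(polys) {
  lo <- t(vapply(polys, function(p) apply(p$vertices, 2, min), numeric(3)))
  hi <- t(vapply(polys, function(p) apply(p$vertices, 2, max), numeric(3)))
  list(lo = lo, hi = hi)
}

#' Detect immediate (contact) neighbours by polygon expansion
#'
#' Edge (i, j) is present iff the two polygons, each expanded in 3D by
#' `expansionUm`, intersect - computed exactly as
#' `polygonPairDistance(i, j) < 2 * expansionUm` (Minkowski-ball
#' equivalence). Candidate pairs are pre-filtered conservatively by centroid
#' distance (<= sum of circumradii + 2r), so no true pair is missed; cheap
#' bounding-box and vertex-pair bounds resolve most candidates before the
#' exact distance is needed.
#'
#' @param polygons a [CellPolygonSet-class].
#' @param expansionUm expansion radius r in micrometres (> 0); default 0.6.
#' @return a [NeighbourGraph-class] with `method = "contact"`.
#' @export
detectContactNeighbours <- function(polygons, expansionUm = 0.6) {
  stopifnot(expansionUm > 0)
  ids <- cellIds(polygons)
  n <- length(ids)
  thr <- 2 * expansionUm
  if (n <= 1)
    return(NeighbourGraph(ids, method = "contact", parameter = expansionUm))
  plist <- polygons@polygons
  cen <- centroids(polygons)
  rad <- vapply(plist, .circumradius, numeric(1))
  bb <- .bboxes(plist)
  edgeA <- character(0); edgeB <- character(0)
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    cd <- sqrt(rowSums(sweep(cen[js, , drop = FALSE], 2, cen[i, ])^2))
    js <- js[cd <= rad[i] + rad[js] + thr]
    if (!length(js)) next
    vi <- plist[[i]]$vertices
    for (j in js) {
      ## lower bound: componentwise bounding-box gap
      gap <- pmax(0, bb$lo[j, ] - bb$hi[i, ], bb$lo[i, ] - bb$hi[j, ])
      if (sqrt(sum(gap^2)) >= thr) next
      ## upper bound: any vertex pair already within 2r
      vj <- plist[[j]]$vertices
      cross2 <- outer(rowSums(vi^2), rowSums(vj^2), "+") -
        2 * tcrossprod(vi, vj)
      if (min(cross2) < thr^2 ||
          convexBodyDistance(vi, vj)$distance < thr) {
        edgeA <- c(edgeA, ids[i]); edgeB <- c(edgeB, ids[j])
      }
    }
  }
  NeighbourGraph(ids, cbind(edgeA, edgeB), method = "contact",
                 parameter = expansionUm)
}

#' Detect neighbours by centroid radius search
#'
#' Computes the Euclidean distance between the centre points of every pair
#' of cells and filters by the given radius: distinct cells within
#' `radiusUm` of each other are neighbours (with `radiusUm = 0` the graph
#' has no edges). Duplicate
#' centroids (distance 0 between distinct ids) do form an edge and are
#' messaged.
#'
#' @param cellCentroids numeric matrix (cells x 3, rownames = cell ids) of
#'   centre points in micrometres.
#' @param radiusUm search radius R in micrometres (>= 0).
#' @return a [NeighbourGraph-class] with `method = "radius"`.
#' @export
detectRadiusNeighbours <- function(cellCentroids, radiusUm) {
  stopifnot(radiusUm >= 0)
  cellCentroids <- as.matrix(cellCentroids)
  ids <- rownames(cellCentroids)
  if (is.null(ids)) stop("cellCentroids must have cell ids as rownames")
  e <- matrix(character(0), 0, 2)
  if (nrow(cellCentroids) > 1 && radiusUm > 0) {
    d <- as.matrix(stats::dist(cellCentroids))
    sel <- which(upper.tri(d) & d <= radiusUm, arr.ind = TRUE)
    if (nrow(sel)) {
      e <- cbind(ids[sel[, 1]], ids[sel[, 2]])
      nz <- d[sel] == 0
      if (any(nz))
        message(sum(nz), " neighbour pair(s) at identical centroids")
    }
  }
  NeighbourGraph(ids, e, method = "radius", parameter = radiusUm)
}

#' Assign mRNA spots to cell volumes
#'
#' Each spot is tested against the (unexpanded) cell polygons by its x, y, z
#' coordinates. A spot inside exactly one hull gets that cell; a spot inside
#' two or more (slightly overlapping hulls) goes to the nearest polygon
#' centroid and is flagged ambiguous; a spot inside none stays unassigned.
#'
#' @param mrnaSpots spot data.frame.
#' @param polygons a [CellPolygonSet-class].
#' @param tol containment tolerance in micrometres.
#' @return the spot data.frame with `cell_id` filled (`""` = unassigned) and
#'   a logical `ambiguous` column; unassigned/ambiguous fractions are
#'   messaged.
#' @export
assignSpotsToCells <- function(mrnaSpots, polygons, tol = 1e-9) {
  ns <- nrow(mrnaSpots)
  mrnaSpots$cell_id <- rep("", ns)
  mrnaSpots$ambiguous <- rep(FALSE, ns)
  if (ns == 0 || length(polygons) == 0) return(mrnaSpots)
  plist <- polygons@polygons
  ids <- cellIds(polygons)
  xyz <- as.matrix(mrnaSpots[, c("x_um", "y_um", "z_um")])
  ord <- order(xyz[, 1])
  xs <- xyz[ord, 1]
  hits <- vector("list", length(plist))   # per polygon: spot indices inside
  bb <- .bboxes(plist)
  for (k in seq_along(plist)) {
    i0 <- findInterval(bb$lo[k, 1] - tol, xs) + 1
    i1 <- findInterval(bb$hi[k, 1] + tol, xs)
    if (i1 < i0) next
    cand <- ord[i0:i1]
    sub <- xyz[cand, , drop = FALSE]
    keep <- sub[, 2] >= bb$lo[k, 2] - tol & sub[, 2] <= bb$hi[k, 2] + tol &
            sub[, 3] >= bb$lo[k, 3] - tol & sub[, 3] <= bb$hi[k, 3] + tol
    cand <- cand[keep]
    if (!length(cand)) next
    inside <- .pointsInHull(xyz[cand, , drop = FALSE], plist[[k]], tol)
    hits[[k]] <- cand[inside]
  }
  nHit <- integer(ns)
  firstHit <- integer(ns)
  for (k in seq_along(hits)) {
    h <- hits[[k]]
    nHit[h] <- nHit[h] + 1L
    firstHit[h[nHit[h] == 1L]] <- k
  }
  single <- nHit == 1L
  mrnaSpots$cell_id[single] <- ids[firstHit[single]]
  multi <- which(nHit > 1L)
  if (length(multi)) {
    cen <- centroids(polygons)
    byCell <- rep(seq_along(hits), lengths(hits))
    spotOf <- unlist(hits)
    keep <- spotOf %in% multi
    spotOf <- spotOf[keep]; byCell <- byCell[keep]
    d2 <- rowSums((xyz[spotOf, , drop = FALSE] -
                   cen[byCell, , drop = FALSE])^2)
    best <- tapply(seq_along(spotOf), spotOf, function(ii)
      byCell[ii][which.min(d2[ii])])
    mrnaSpots$cell_id[as.integer(names(best))] <- ids[as.integer(best)]
    mrnaSpots$ambiguous[multi] <- TRUE
  }
  unass <- mean(nHit == 0L)
  message(sprintf(
    "assigned %d/%d spots (%.2f%% unassigned, %.2f%% ambiguous)",
    sum(nHit > 0L), ns, 100 * unass, 100 * mean(nHit > 1L)))
  mrnaSpots
}

#' Per-cell counts from assigned spots
#'
#' Groups assigned mRNA spots into a cells-by-genes count table over the
#' given cell universe (unassigned spots are dropped).
#'
#' @param assignedSpots output of [assignSpotsToCells()].
#' @param cellCentroids matrix of per-cell centroids (rownames = cell ids),
#'   e.g. `centroids(polygons)`.
#' @param genes optional gene universe (defaults to genes seen).
#' @return a [CellExpression-class].
#' @export
countsFromSpots <- function(assignedSpots, cellCentroids,
                            genes = NULL) {
  cellCentroids <- as.matrix(cellCentroids)
  ids <- rownames(cellCentroids)
  if (is.null(genes))
    genes <- sort(unique(assignedSpots$gene[assignedSpots$gene != ""]))
  keep <- assignedSpots$cell_id %in% ids
  tab <- table(factor(assignedSpots$cell_id[keep], levels = ids),
               factor(assignedSpots$gene[keep], levels = genes))
  cm <- matrix(as.integer(tab), nrow = length(ids),
               dimnames = list(ids, genes))
  CellExpression(cm, cellCentroids)
}

#' Neighbour-count histogram
#'
#' Tabulates the per-cell neighbour number of a graph (degree), including
#' isolated cells at degree 0.
#'
#' @param graph a [NeighbourGraph-class].
#' @return named integer vector, names = degree, values = number of cells;
#'   the counts sum to the number of cells.
#' @export
neighbourCountHistogram <- function(graph) {
  deg <- neighbourCounts(graph)
  t <- table(deg)
  stats::setNames(as.integer(t), names(t))
}
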