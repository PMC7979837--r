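#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame SimpleList
NULL

## ---------------------------------------------------------------------------
## RunConfig
## ---------------------------------------------------------------------------

#' Run configuration
#'
#' Holds the tunable parameters of the analysis pipeline. The polygon
#' expansion used for contact-neighbour detection can be given either as an
#' absolute distance in micrometres (`expansionUm`, default 0.6) or as a
#' fraction of the median cell diameter (`expansionFraction`, roughly 0.1 for
#' a blastoderm cell); exactly one of the two may be active.
#'
#' @slot expansionUm polygon expansion radius in micrometres (NA when the
#'   fractional form is used).
#' @slot expansionFraction expansion as a fraction of the median cell
#'   diameter (NA when the absolute form is used).
#' @slot radiusUm search radius in micrometres for radius-based
#'   neighbourhoods (NA when unused).
#' @slot pvGroupMeanThreshold minimum neighbour-group mean mRNA count for a
#'   cell to retain its raw PV score; below it the filtered PV is 0.
#' @slot histogramBinWidth width of the mRNA-count histogram bins.
#' @slot seed integer seed controlling all stochastic stages.
#' @export
setClass("RunConfig",
  representation(
    expansionUm = "numeric",
    expansionFraction = "numeric",
    radiusUm = "numeric",
    pvGroupMeanThreshold = "numeric",
    histogramBinWidth = "integer",
    seed = "integer"
  ),
  prototype(
    expansionUm = 0.6,
    expansionFraction = NA_real_,
    radiusUm = NA_real_,
    pvGroupMeanThreshold = 1,
    histogramBinWidth = 5L,
    seed = 1L
  )
)

setValidity("RunConfig", function(object) {
  msg <- character()
  hasAbs <- !is.na(object@expansionUm)
  hasFrac <- !is.na(object@expansionFraction)
  if (hasAbs && hasFrac)
    msg <- c(msg, "exactly one of expansionUm / expansionFraction may be set")
  if (!hasAbs && !hasFrac)
    msg <- c(msg, "one of expansionUm / expansionFraction must be set")
  if (hasAbs && (!is.finite(object@expansionUm) || object@expansionUm <= 0))
    msg <- c(msg, "expansionUm must be finite and > 0")
  if (hasFrac && (!is.finite(object@expansionFraction) ||
                  object@expansionFraction <= 0))
    msg <- c(msg, "expansionFraction must be finite and > 0")
  if (!is.na(object@radiusUm) &&
      (!is.finite(object@radiusUm) || object@radiusUm < 0))
    msg <- c(msg, "radiusUm must be finite and >= 0")
  if (!is.finite(object@pvGroupMeanThreshold) ||
      object@pvGroupMeanThreshold < 0)
    msg <- c(msg, "pvGroupMeanThreshold must be finite and >= 0")
  if (object@histogramBinWidth < 1L)
    msg <- c(msg, "histogramBinWidth must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Create a run configuration
#'
#' @param expansionUm polygon expansion radius in micrometres; default 0.6.
#' @param expansionFraction alternative expansion as a fraction of the median
#'   cell diameter; mutually exclusive with `expansionUm`.
#' @param radiusUm optional centroid search radius in micrometres.
#' @param pvGroupMeanThreshold PV expression filter threshold; default 1.
#' @param histogramBinWidth histogram bin width; default 5.
#' @param seed integer seed.
#' @return a [RunConfig-class] object.
#' @examples
#' cfg <- RunConfig()
#' expansionDistance(cfg)
#' @export
RunConfig <- function(expansionUm = 0.6, expansionFraction = NA_real_,
                      radiusUm = NA_real_, pvGroupMeanThreshold = 1,
                      histogramBinWidth = 5L, seed = 1L) {
  if (!is.na(expansionFraction) && missing(expansionUm))
    expansionUm <- NA_real_
  new("RunConfig",
      expansionUm = as.numeric(expansionUm),
      expansionFraction = as.numeric(expansionFraction),
      radiusUm = as.numeric(radiusUm),
      pvGroupMeanThreshold = as.numeric(pvGroupMeanThreshold),
      histogramBinWidth = as.integer(histogramBinWidth),
      seed = as.integer(seed))
}

#' Effective polygon expansion distance
#'
#' Resolves a configuration's expansion to micrometres. When the fractional
#' form is active, `medianDiameterUm` (the median cell diameter of the data
#' set at hand) must be supplied.
#'
#' @param config a [RunConfig-class].
#' @param medianDiameterUm median cell diameter in micrometres.
#' @return expansion radius in micrometres.
#' @export
expansionDistance <- function(config, medianDiameterUm = NULL) {
  if (!is.na(config@expansionUm)) return(config@expansionUm)
  if (is.null(medianDiameterUm))
    stop("expansionFraction is set; medianDiameterUm is required")
  config@expansionFraction * medianDiameterUm
}

setMethod("show", "RunConfig", function(object) {
  exp <- if (!is.na(object@expansionUm))
    sprintf("%g um", object@expansionUm)
  else
    sprintf("%g x median cell diameter", object@expansionFraction)
  cat("RunConfig\n",
      "  expansion:            ", exp, "\n",
      "  radiusUm:             ", object@radiusUm, "\n",
      "  pvGroupMeanThreshold: ", object@pvGroupMeanThreshold, "\n",
      "  histogramBinWidth:    ", object@histogramBinWidth, "\n",
      "  seed:                 ", object@seed, "\n", sep = "")
})

## ---------------------------------------------------------------------------
## CellPolygonSet
## ---------------------------------------------------------------------------

#' Set of per-cell 3D convex polygons
#'
#' One convex hull per cell, built from that cell's membrane spots. Each
#' polygon is a list with elements `vertices` (matrix, micrometres), `faces`
#' (triangle vertex-index matrix), `normals` and `offsets` (outward face
#' half-spaces, `normals %*% x <= offsets` inside), `centroid`, `volumeUm3`
#' and `sourceSpotCount`. Cells whose spots were too degenerate to span a 3D
#' hull (fewer than four non-coplanar points) are listed in `degenerate` and
#' carry no polygon.
#'
#' @slot polygons named list of polygon lists, one per non-degenerate cell.
#' @slot degenerate character vector of degenerate cell ids.
#' @export
setClass("CellPolygonSet",
  representation(polygons = "list", degenerate = "character"))

setValidity("CellPolygonSet", function(object) {
  msg <- character()
  if (length(object@polygons) &&
      (is.null(names(object@polygons)) || anyDuplicated(names(object@polygons))))
    msg <- c(msg, "polygons must be uniquely named by cell id")
  if (any(names(object@polygons) %in% object@degenerate))
    msg <- c(msg, "a cell cannot be both degenerate and polygonal")
  if (length(msg)) msg else TRUE
})

#' @describeIn CellPolygonSet-class cell ids with a polygon.
#' @param x a `CellPolygonSet`.
#' @export
setMethod("cellIds", "CellPolygonSet", function(x) names(x@polygons))

#' @describeIn CellPolygonSet-class degenerate cell ids.
#' @export
setMethod("degenerateCells", "CellPolygonSet", function(x) x@degenerate)

#' @describeIn CellPolygonSet-class matrix of polygon centroids (um).
#' @export
setMethod("centroids", "CellPolygonSet", function(x) {
  m <- do.call(rbind, lapply(x@polygons, `[[`, "centroid"))
  if (is.null(m)) m <- matrix(numeric(0), 0, 3)
  rownames(m) <- names(x@polygons)
  colnames(m) <- c("x_um", "y_um", "z_um")
  m
})

#' @describeIn CellPolygonSet-class named vector of hull volumes (um^3).
#' @export
setMethod("volumes", "CellPolygonSet", function(x)
  vapply(x@polygons, `[[`, numeric(1), "volumeUm3"))

#' @describeIn CellPolygonSet-class extract one cell's polygon.
#' @param id a cell id.
#' @export
setMethod("polygonOf", "CellPolygonSet", function(x, id) {
  p <- x@polygons[[id]]
  if (is.null(p)) stop("no polygon for cell '", id, "'")
  p
})

setMethod("show", "CellPolygonSet", function(object) {
  cat("CellPolygonSet with", length(object@polygons), "cell polygons",
      sprintf("(%d degenerate cells)\n", length(object@degenerate)))
  if (length(object@polygons)) {
    v <- volumes(object)
    cat(sprintf("  volume (um^3): median %.2f, range [%.2f, %.2f]\n",
                stats::median(v), min(v), max(v)))
  }
})

#' Length of a CellPolygonSet
#' @param x a `CellPolygonSet`.
#' @export
setMethod("length", "CellPolygonSet", function(x) length(x@polygons))

## ---------------------------------------------------------------------------
## NeighbourGraph
## ---------------------------------------------------------------------------

#' Cell neighbour graph
#'
#' Symmetric, irreflexive adjacency over cell ids, from either the
#' contact method (expanded-polygon intersection) or a centroid radius
#' search. Edges are stored as unordered pairs, lexicographically sorted
#' within and across rows.
#'
#' @slot cells character vector of cell ids (nodes).
#' @slot edges two-column character matrix of unordered cell-id pairs.
#' @slot method `"contact"` or `"radius"`.
#' @slot parameter the expansion radius r (contact) or search radius R
#'   (radius), in micrometres.
#' @export
setClass("NeighbourGraph",
  representation(cells = "character", edges = "matrix",
                 method = "character", parameter = "numeric"))

## canonical form: each row sorted, rows unique and sorted
.canonicalEdges <- function(e) {
  e <- as.matrix(e)
  if (nrow(e) == 0) {
    e <- matrix(character(0), 0, 2)
  } else {
    swap <- e[, 1] > e[, 2]
    e[swap, ] <- e[swap, c(2, 1), drop = FALSE]
    e <- unique(e)
    e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  }
  colnames(e) <- c("cell_a", "cell_b")
  rownames(e) <- NULL
  e
}

setValidity("NeighbourGraph", function(object) {
  msg <- character()
  e <- object@edges
  if (ncol(e) != 2) msg <- c(msg, "edges must have two columns")
  if (nrow(e)) {
    if (any(e[, 1] == e[, 2])) msg <- c(msg, "self-edges are not allowed")
    if (!all(e %in% object@cells))
      msg <- c(msg, "edge endpoints must be graph cells")
    if (any(e[, 1] > e[, 2]) || anyDuplicated(e))
      msg <- c(msg, "edges must be canonical unordered pairs")
  }
  if (anyDuplicated(object@cells)) msg <- c(msg, "duplicate cell ids")
  if (!object@method %in% c("contact", "radius", "truth"))
    msg <- c(msg, "method must be contact, radius or truth")
  if (length(msg)) msg else TRUE
})

#' Create a neighbour graph
#'
#' @param cells character vector of cell ids.
#' @param edges two-column matrix (or data.frame) of cell-id pairs; order
#'   within a pair is irrelevant and duplicates collapse.
#' @param method `"contact"`, `"radius"` or `"truth"`.
#' @param parameter method parameter in micrometres (expansion r or radius R).
#' @return a [NeighbourGraph-class].
#' @export
NeighbourGraph <- function(cells, edges = matrix(character(0), 0, 2),
                           method = "contact", parameter = NA_real_) {
  new("NeighbourGraph", cells = as.character(cells),
      edges = .canonicalEdges(edges), method = method,
      parameter = as.numeric(parameter))
}

#' @describeIn NeighbourGraph-class the cell ids (nodes).
#' @param x a `NeighbourGraph`.
#' @export
setMethod("cellIds", "NeighbourGraph", function(x) x@cells)

#' @describeIn NeighbourGraph-class the canonical edge matrix.
#' @export
setMethod("edges", "NeighbourGraph", function(x) x@edges)

#' @describeIn NeighbourGraph-class detection method name.
#' @export
setMethod("graphMethod", "NeighbourGraph", function(x) x@method)

#' @describeIn NeighbourGraph-class named vector of per-cell degrees
#'   (0 for isolated cells).
#' @export
setMethod("neighbourCounts", "NeighbourGraph", function(x) {
  deg <- stats::setNames(integer(length(x@cells)), x@cells)
  if (nrow(x@edges)) {
    t <- table(factor(c(x@edges[, 1], x@edges[, 2]), levels = x@cells))
    deg[names(t)] <- as.integer(t)
  }
  deg
})

#' @describeIn NeighbourGraph-class neighbours of one cell.
#' @param id a cell id.
#' @export
setMethod("neighboursOf", "NeighbourGraph", function(x, id) {
  if (!id %in% x@cells) stop("cell '", id, "' is not in the graph")
  e <- x@edges
  sort(c(e[e[, 1] == id, 2], e[e[, 2] == id, 1]))
})

setMethod("show", "NeighbourGraph", function(object) {
  cat(sprintf("NeighbourGraph (%s, parameter %g um): %d cells, %d edges\n",
              object@method, object@parameter, length(object@cells),
              nrow(object@edges)))
})

## ---------------------------------------------------------------------------
## CellExpression
## ---------------------------------------------------------------------------

#' Per-cell, per-gene mRNA counts with centroids
#'
#' A [SummarizedExperiment::SummarizedExperiment] with genes as rows, cells
#' as columns, an integer `counts` assay, and cell centroids
#' (`centroid_x_um`, `centroid_y_um`, `centroid_z_um`) in `colData`.
#'
#' @export
setClass("CellExpression", contains = "SummarizedExperiment")

setValidity("CellExpression", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "a 'counts' assay is required")
  else {
    m <- assay(object, "counts")
    if (any(!is.finite(m)) || any(m < 0) || any(m != round(m)))
      msg <- c(msg, "counts must be nonnegative integers")
  }
  need <- c("centroid_x_um", "centroid_y_um", "centroid_z_um")
  if (!all(need %in% colnames(colData(object))))
    msg <- c(msg, paste("colData must contain", paste(need, collapse = ", ")))
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "cell ids (colnames) must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Create a CellExpression object
#'
#' @param counts matrix of nonnegative integer counts with cells in rows
#'   (rownames = cell ids) and genes in columns, i.e. the layout of the
#'   counts CSV; it is transposed into the genes-by-cells assay.
#' @param centroids numeric matrix of per-cell 3D centroids in micrometres
#'   (one row per cell, same order/rownames as `counts`).
#' @return a [CellExpression-class].
#' @examples
#' counts <- matrix(c(0L, 3L, 5L, 1L), 2, 2,
#'                  dimnames = list(c("c1", "c2"), c("gA", "gB")))
#' cents <- matrix(rnorm(6), 2, 3, dimnames = list(c("c1", "c2"), NULL))
#' ce <- CellExpression(counts, cents)
#' countsMatrix(ce)
#' @export
CellExpression <- function(counts, centroids) {
  counts <- as.matrix(counts)
  centroids <- as.matrix(centroids)
  if (nrow(counts) != nrow(centroids))
    stop("counts and centroids must describe the same cells")
  if (is.null(rownames(counts)))
    stop("counts must have cell ids as rownames")
  if (!is.null(rownames(centroids)) &&
      !identical(rownames(centroids), rownames(counts)))
    stop("centroid rownames disagree with counts rownames")
  storage.mode(counts) <- "integer"
  cd <- DataFrame(centroid_x_um = as.numeric(centroids[, 1]),
                  centroid_y_um = as.numeric(centroids[, 2]),
                  centroid_z_um = as.numeric(centroids[, 3]),
                  row.names = rownames(counts))
  se <- SummarizedExperiment(assays = SimpleList(counts = t(counts)),
                             colData = cd)
  new("CellExpression", se)
}

#' @describeIn CellExpression-class cell ids.
#' @param x a `CellExpression`.
#' @export
setMethod("cellIds", "CellExpression", function(x) colnames(x))

#' @describeIn CellExpression-class per-cell centroid matrix (um).
#' @export
setMethod("centroids", "CellExpression", function(x) {
  cd <- colData(x)
  m <- cbind(cd$centroid_x_um, cd$centroid_y_um, cd$centroid_z_um)
  dimnames(m) <- list(colnames(x), c("x_um", "y_um", "z_um"))
  m
})

#' Cells-by-genes count matrix
#'
#' @param x a [CellExpression-class].
#' @return integer matrix, cells in rows, genes in columns.
#' @export
countsMatrix <- function(x) t(assay(x, "counts"))

#' Gene names of a CellExpression
#' @param x a [CellExpression-class].
#' @export
geneNames <- function(x) rownames(x)

## ---------------------------------------------------------------------------
## SyntheticEmbryo
## ---------------------------------------------------------------------------

#' Synthetic blastoderm embryo
#'
#' Bundle of a simulated embryo's ground truth and emitted spot tables: the
#' prism cell lattice, the true lattice adjacency, the true per-cell counts,
#' and the membrane/mRNA spot tables that emulate segmentation-software
#' exports.
#'
#' @slot cells data.frame with one row per cell: `cell_id`, lattice indices,
#'   footprint centre `x_um`/`y_um`, `z_basal_um`, `z_apical_um`, AP position
#'   `ap` in \[0,1\], and list-column `footprint` (2D hexagon vertex matrix).
#' @slot trueAdjacency [NeighbourGraph-class] of lattice contacts.
#' @slot trueCounts [CellExpression-class] of generated counts.
#' @slot membraneSpots,mrnaSpots spot data.frames in the spots-CSV schema
#'   (mRNA spots carry the generating cell in `cell_id`).
#' @slot params the [SimParams()] list used.
#' @slot seed integer seed used.
#' @export
setClass("SyntheticEmbryo",
  representation(cells = "data.frame", trueAdjacency = "NeighbourGraph",
                 trueCounts = "CellExpression", membraneSpots = "data.frame",
                 mrnaSpots = "data.frame", params = "list", seed = "integer"))

#' @describeIn SyntheticEmbryo-class cell ids.
#' @param x a `SyntheticEmbryo`.
#' @export
setMethod("cellIds", "SyntheticEmbryo", function(x) x@cells$cell_id)

#' @describeIn SyntheticEmbryo-class ground-truth adjacency.
#' @export
setMethod("trueAdjacency", "SyntheticEmbryo", function(x) x@trueAdjacency)

#' @describeIn SyntheticEmbryo-class ground-truth counts.
#' @export
setMethod("trueCounts", "SyntheticEmbryo", function(x) x@trueCounts)

#' @describeIn SyntheticEmbryo-class membrane spot table.
#' @export
setMethod("membraneSpots", "SyntheticEmbryo", function(x) x@membraneSpots)

#' @describeIn SyntheticEmbryo-class mRNA spot table.
#' @export
setMethod("mrnaSpots", "SyntheticEmbryo", function(x) x@mrnaSpots)

setMethod("show", "SyntheticEmbryo", function(object) {
  cat(sprintf(paste0("SyntheticEmbryo: %d cells, %d genes, ",
                     "%d membrane spots, %d mRNA spots (seed %d)\n"),
              nrow(object@cells), nrow(object@trueCounts),
              nrow(object@membraneSpots), nrow(object@mrnaSpots),
              object@seed))
})
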