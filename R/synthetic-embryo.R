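## Synthetic cellular-blastoderm embryo.
##
## A columnar monolayer of hexagonal-prism cells on a regular hex lattice
## (the blastoderm epithelium analysed between the apical surface and the
## basal limit of membrane ingression). Defaults follow the scale of a real
## segmented embryo: ~2000 cells of ~6 um diameter over a 9.6 um deep stack,
## ~40 membrane spots per cell (~80,000 in total), with anterior-posterior
## stripe (pair-rule-like) and broad-domain (gap-gene-like) per-gene count
## patterns and overdispersed count noise. Lattice centres are regular;
## stochasticity enters through membrane-spot jitter and count sampling, so
## the prism partition remains exact ground truth for adjacency and
## spot-to-cell assignment.

#' Pattern specification for one gene
#'
#' Describes a deterministic anterior-posterior mean-count profile; counts
#' are then drawn around it by [sampleCounts()].
#'
#' @param gene gene name.
#' @param profile one of `"stripes"` (sum of Gaussian bumps at evenly
#'   spaced AP centres, pair-rule-like), `"broad_domain"` (logistic-edged
#'   plateau, gap-gene-like), `"gradient"` (exponential AP decay),
#'   `"uniform"`, `"off"`.
#' @param peakMeanCount mean count at profile peak (mRNA/cell).
#' @param nStripes number of stripes; default 7.
#' @param stripeWidth Gaussian sd of a stripe in AP units (\[0,1\] axis).
#' @param centre,width centre and full width of a broad domain (AP units).
#' @param edgeSoftness logistic edge scale of a broad domain (AP units);
#'   gives the graded rather than sharp domain borders seen in real data.
#' @param decayLength exponential decay length of a gradient (AP units).
#' @return a `PatternSpec` list.
#' @export
patternSpec <- function(gene,
                        profile = c("stripes", "broad_domain", "gradient",
                                    "uniform", "off"),
                        peakMeanCount = 60, nStripes = 7L,
                        stripeWidth = 0.025, centre = 0.5, width = 0.2,
                        edgeSoftness = 0.02, decayLength = 0.3) {
  profile <- match.arg(profile)
  stopifnot(peakMeanCount >= 0, nStripes >= 1L)
  structure(list(gene = gene, profile = profile,
                 peakMeanCount = peakMeanCount, nStripes = as.integer(nStripes),
                 stripeWidth = stripeWidth, centre = centre, width = width,
                 edgeSoftness = edgeSoftness, decayLength = decayLength),
            class = "PatternSpec")
}

#' Default five-gene blastoderm panel
#'
#' One seven-stripe pair-rule-like gene and four gap-gene-like domains
#' spread along the AP axis, with peak means of order 60-80 mRNA/cell.
#'
#' @return list of [patternSpec()] objects.
#' @export
defaultGenePanel <- function() {
  list(
    patternSpec("eve", "stripes", peakMeanCount = 60),
    patternSpec("hb",  "broad_domain", centre = 0.22, width = 0.34,
                peakMeanCount = 60),
    patternSpec("Kr",  "broad_domain", centre = 0.50, width = 0.20,
                peakMeanCount = 80),
    patternSpec("kni", "broad_domain", centre = 0.68, width = 0.14,
                peakMeanCount = 60),
    patternSpec("gt",  "broad_domain", centre = 0.85, width = 0.12,
                peakMeanCount = 60))
}

#' Simulation parameters
#'
#' @param nCellsTarget number of cells; default 2000.
#' @param cellDiameterUm centre-to-centre cell spacing (= flat-to-flat
#'   hexagon diameter) in micrometres; default 6.
#' @param depthUm apical-basal prism depth in micrometres; default 9.6
#'   (a 48-slice stack at 200 nm).
#' @param membraneSpotsPerCell membrane spots per cell; default 40
#'   (~80,000 spots for ~2000 cells).
#' @param membraneJitterUm isotropic Gaussian sd of membrane-spot
#'   displacement off the prism surface; default 0.1.
#' @param genes list of [patternSpec()]; default [defaultGenePanel()].
#' @param countNoise `"negative_binomial"` (default) or `"poisson"`.
#' @param nbFano variance/mean of the negative-binomial noise; default 3.
#' @param mrnaInsetUm inset of mRNA spots from the prism faces; default 0.5
#'   (chosen to dominate the membrane-jitter scale so inset spots stay
#'   inside jitter-eroded hulls).
#' @param mask `"rectangle"` (default) or `"ellipse"` sheet outline.
#' @return a validated `SimParams` list.
#' @export
SimParams <- function(nCellsTarget = 2000L, cellDiameterUm = 6,
                      depthUm = 9.6, membraneSpotsPerCell = 40L,
                      membraneJitterUm = 0.1, genes = defaultGenePanel(),
                      countNoise = c("negative_binomial", "poisson"),
                      nbFano = 3, mrnaInsetUm = 0.5,
                      mask = c("rectangle", "ellipse")) {
  countNoise <- match.arg(countNoise)
  mask <- match.arg(mask)
  stopifnot(cellDiameterUm > 0, depthUm > 0, membraneSpotsPerCell >= 1,
            membraneJitterUm >= 0, nbFano > 1 || countNoise == "poisson",
            mrnaInsetUm >= 0)
  if (membraneJitterUm >= cellDiameterUm / 2)
    stop("membraneJitterUm must be smaller than half the cell diameter")
  if (nCellsTarget < 7L)
    stop("nCellsTarget must be at least 7 (one cell and its six neighbours)")
  structure(list(nCellsTarget = as.integer(nCellsTarget),
                 cellDiameterUm = cellDiameterUm, depthUm = depthUm,
                 membraneSpotsPerCell = as.integer(membraneSpotsPerCell),
                 membraneJitterUm = membraneJitterUm, genes = genes,
                 countNoise = countNoise, nbFano = nbFano,
                 mrnaInsetUm = mrnaInsetUm, mask = mask),
            class = "SimParams")
}

## pointy-top hexagon (vertices at 30 + 60k degrees) with flat-to-flat
## diameter s about (cx, cy); neighbouring footprints share full edges
.hexFootprint <- function(cx, cy, s) {
  R <- s / sqrt(3)
  ang <- (30 + 60 * 0:5) * pi / 180
  cbind(x = cx + R * cos(ang), y = cy + R * sin(ang))
}

#' Generate the cell lattice and its ground-truth adjacency
#'
#' Hexagonally packed prism cells over a rectangular (or ellipse-masked)
#' sheet. True adjacency joins cells sharing a lattice edge; interior cells
#' have exactly six true neighbours, boundary cells fewer. The lattice is
#' deterministic: positional noise is applied later, at the membrane-spot
#' stage, so the prisms remain an exact non-overlapping partition.
#'
#' @param params a [SimParams()] list.
#' @return list with `cells` (data.frame: `cell_id`, `row`, `col`, `x_um`,
#'   `y_um`, `z_basal_um`, `z_apical_um`, `ap`, list-column `footprint`) and
#'   `adjacency` (a [NeighbourGraph-class], method `"truth"`).
#' @export
generateLattice <- function(params) {
  s <- params$cellDiameterUm
  n <- params$nCellsTarget
  dy <- s * sqrt(3) / 2
  nGrid <- if (params$mask == "ellipse") ceiling(n * 4 / pi) else n
  ncols <- max(3L, ceiling(sqrt(2 * nGrid)))
  nrows <- max(3L, ceiling(nGrid / ncols))
  grid <- expand.grid(col = seq_len(ncols) - 1L, row = seq_len(nrows) - 1L)
  grid$x <- (grid$col + 0.5 * (grid$row %% 2)) * s
  grid$y <- grid$row * dy
  if (params$mask == "ellipse") {
    cx <- mean(range(grid$x)); cy <- mean(range(grid$y))
    a <- diff(range(grid$x)) / 2 + s / 4
    b <- diff(range(grid$y)) / 2 + s / 4
    grid <- grid[((grid$x - cx) / a)^2 + ((grid$y - cy) / b)^2 <= 1, ]
  } else {
    grid <- utils::head(grid, n)
  }
  grid$cell_id <- sprintf("cell_%05d", seq_len(nrow(grid)))
  ap <- (grid$x - min(grid$x)) / max(diff(range(grid$x)), 1e-12)
  cells <- data.frame(cell_id = grid$cell_id, row = grid$row, col = grid$col,
                      x_um = grid$x, y_um = grid$y, z_basal_um = 0,
                      z_apical_um = params$depthUm, ap = ap,
                      stringsAsFactors = FALSE)
  cells$footprint <- lapply(seq_len(nrow(cells)), function(i)
    .hexFootprint(cells$x_um[i], cells$y_um[i], s))

  ## lattice-edge adjacency via (row, col) offsets (odd rows shifted +x)
  key <- paste(grid$row, grid$col)
  idOf <- stats::setNames(grid$cell_id, key)
  eA <- character(0); eB <- character(0)
  for (i in seq_len(nrow(grid))) {
    r <- grid$row[i]; cc <- grid$col[i]
    d <- if (r %% 2 == 1) c(0L, 1L) else c(-1L, 0L)
    nb <- rbind(c(r, cc + 1L), c(r + 1L, cc + d[1]), c(r + 1L, cc + d[2]))
    k <- paste(nb[, 1], nb[, 2])
    hit <- k %in% key
    if (any(hit)) {
      eA <- c(eA, rep(grid$cell_id[i], sum(hit)))
      eB <- c(eB, idOf[k[hit]])
    }
  }
  adjacency <- NeighbourGraph(cells$cell_id, cbind(eA, eB),
                              method = "truth", parameter = NA_real_)
  list(cells = cells, adjacency = adjacency)
}

#' Mean-count expression profile along the AP axis
#'
#' Deterministic mean mRNA count of a gene at a normalised
#' anterior-posterior position.
#'
#' @param spec a [patternSpec()].
#' @param apPosition AP positions in \[0, 1\] (vectorised).
#' @return nonnegative mean counts.
#' @export
expressionProfile <- function(spec, apPosition) {
  stopifnot(all(apPosition >= 0 & apPosition <= 1))
  p <- spec$peakMeanCount
  switch(spec$profile,
    off = rep(0, length(apPosition)),
    uniform = rep(p, length(apPosition)),
    gradient = p * exp(-apPosition / spec$decayLength),
    stripes = {
      centres <- seq(0.15, 0.92, length.out = spec$nStripes)
      m <- vapply(centres, function(cc)
        exp(-(apPosition - cc)^2 / (2 * spec$stripeWidth^2)),
        numeric(length(apPosition)))
      p * pmin(1, rowSums(matrix(m, ncol = spec$nStripes)))
    },
    broad_domain = {
      lo <- spec$centre - spec$width / 2
      hi <- spec$centre + spec$width / 2
      p * stats::plogis((apPosition - lo) / spec$edgeSoftness) *
        stats::plogis((hi - apPosition) / spec$edgeSoftness)
    })
}

#' Draw per-cell counts around the pattern profiles
#'
#' Counts are Poisson, or negative binomial with variance `nbFano` times
#' the mean (size parameter mu / (nbFano - 1)).
#'
#' @param cells lattice cell data.frame (from [generateLattice()]).
#' @param specs list of [patternSpec()].
#' @param countNoise `"poisson"` or `"negative_binomial"`.
#' @param seed integer seed.
#' @param nbFano negative-binomial variance/mean ratio.
#' @return a [CellExpression-class] with prism-centre centroids.
#' @export
sampleCounts <- function(cells, specs, countNoise = "negative_binomial",
                         seed = 1L, nbFano = 3) {
  set.seed(seed)
  n <- nrow(cells)
  cm <- matrix(0L, n, length(specs),
               dimnames = list(cells$cell_id,
                               vapply(specs, `[[`, character(1), "gene")))
  for (g in seq_along(specs)) {
    mu <- expressionProfile(specs[[g]], cells$ap)
    cnt <- integer(n)
    pos <- mu > 1e-12
    if (any(pos)) {
      cnt[pos] <- if (countNoise == "poisson") {
        stats::rpois(sum(pos), mu[pos])
      } else {
        stats::rnbinom(sum(pos), mu = mu[pos],
                       size = mu[pos] / (nbFano - 1))
      }
    }
    cm[, g] <- cnt
  }
  cents <- cbind(cells$x_um, cells$y_um,
                 (cells$z_basal_um + cells$z_apical_um) / 2)
  rownames(cents) <- cells$cell_id
  CellExpression(cm, cents)
}

## uniform point in the triangle (a, b, c): square-root warping of two
## uniforms preserves uniformity
.uniformInTriangle <- function(k, a, b, c) {
  r1 <- sqrt(stats::runif(k)); r2 <- stats::runif(k)
  (1 - r1) %o% a + (r1 * (1 - r2)) %o% b + (r1 * r2) %o% c
}

#' Sample membrane spots on the prism surfaces
#'
#' Emulates low-threshold spot detection in a membrane channel: per cell,
#' the 12 prism corner vertices (tricellular-junction analogue, spanning
#' the full cell extent), plus points on the lateral faces and on the
#' apical and basal rims, all displaced by isotropic Gaussian jitter.
#'
#' @param cells lattice cell data.frame.
#' @param params a [SimParams()] list.
#' @param seed integer seed.
#' @return membrane spot data.frame (spots-CSV schema), with `cell_id` set.
#' @export
sampleMembraneSpots <- function(cells, params, seed = 1L) {
  set.seed(seed)
  m <- params$membraneSpotsPerCell
  depth <- params$depthUm
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    hx <- cells$footprint[[i]]
    nxt <- c(2:6, 1)
    nCorner <- min(12L, m)
    corner <- cbind(rbind(hx, hx)[seq_len(nCorner), , drop = FALSE],
                    z = rep(c(depth, 0), each = 6)[seq_len(nCorner)])
    nFree <- m - nCorner
    nRim <- round(0.3 * nFree)
    nLat <- nFree - nRim
    pts <- corner
    if (nLat > 0) {
      e <- sample.int(6, nLat, replace = TRUE)
      t <- stats::runif(nLat)
      lat <- cbind(hx[e, 1] + t * (hx[nxt[e], 1] - hx[e, 1]),
                   hx[e, 2] + t * (hx[nxt[e], 2] - hx[e, 2]),
                   stats::runif(nLat, 0, depth))
      pts <- rbind(pts, lat)
    }
    if (nRim > 0) {
      e <- sample.int(6, nRim, replace = TRUE)
      t <- stats::runif(nRim)
      rim <- cbind(hx[e, 1] + t * (hx[nxt[e], 1] - hx[e, 1]),
                   hx[e, 2] + t * (hx[nxt[e], 2] - hx[e, 2]),
                   sample(c(0, depth), nRim, replace = TRUE))
      pts <- rbind(pts, rim)
    }
    if (params$membraneJitterUm > 0)
      pts <- pts + matrix(stats::rnorm(length(pts), 0,
                                       params$membraneJitterUm), nrow(pts))
    out[[i]] <- data.frame(
      spot_id = sprintf("%s_m%02d", cells$cell_id[i], seq_len(m)),
      kind = "membrane", gene = "", x_um = pts[, 1], y_um = pts[, 2],
      z_um = pts[, 3], intensity = NA_real_, cell_id = cells$cell_id[i],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sample mRNA spots inside the cell prisms
#'
#' For each cell and gene, exactly the true count of points, uniform inside
#' the prism inset by `params$mrnaInsetUm` from every face (so boundary
#' ambiguity cannot arise). The generating cell is recorded in
#' `true_cell_id`; `cell_id` is left unassigned for the pipeline to fill.
#'
#' @param cells lattice cell data.frame.
#' @param trueCounts a [CellExpression-class].
#' @param params a [SimParams()] list.
#' @param seed integer seed.
#' @return mRNA spot data.frame with an extra `true_cell_id` column.
#' @export
sampleMrnaSpots <- function(cells, trueCounts, params, seed = 1L) {
  set.seed(seed)
  cm <- countsMatrix(trueCounts)
  genes <- colnames(cm)
  inset <- params$mrnaInsetUm
  apothem <- params$cellDiameterUm / 2
  f <- max(0, (apothem - inset) / apothem)
  out <- list()
  for (i in seq_len(nrow(cells))) {
    tot <- sum(cm[cells$cell_id[i], ])
    if (tot == 0) next
    hx <- cells$footprint[[i]]
    ctr <- c(cells$x_um[i], cells$y_um[i])
    hxIn <- sweep(sweep(hx, 2, ctr) * f, 2, ctr, "+")
    tri <- sample.int(6, tot, replace = TRUE)
    nxt <- c(2:6, 1)
    xy <- matrix(0, tot, 2)
    for (k in unique(tri)) {
      sel <- tri == k
      xy[sel, ] <- .uniformInTriangle(sum(sel), ctr, hxIn[k, ],
                                      hxIn[nxt[k], ])
    }
    z <- stats::runif(tot, cells$z_basal_um[i] + inset,
                      cells$z_apical_um[i] - inset)
    gene <- rep(genes, cm[cells$cell_id[i], ])
    out[[length(out) + 1]] <- data.frame(
      spot_id = sprintf("%s_r%04d", cells$cell_id[i], seq_len(tot)),
      kind = "mrna", gene = gene, x_um = xy[, 1], y_um = xy[, 2], z_um = z,
      intensity = NA_real_, cell_id = "",
      true_cell_id = cells$cell_id[i], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(spot_id = character(0), kind = character(0),
                      gene = character(0), x_um = numeric(0),
                      y_um = numeric(0), z_um = numeric(0),
                      intensity = numeric(0), cell_id = character(0),
                      true_cell_id = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a full synthetic embryo
#'
#' Runs lattice generation, count sampling, membrane-spot and mRNA-spot
#' sampling under one seed. Per-stage seeds are derived from `seed` by
#' fixed offsets so stages can be reproduced in isolation.
#'
#' @param params a [SimParams()] list.
#' @param seed integer master seed.
#' @return a [SyntheticEmbryo-class].
#' @examples
#' emb <- simulateEmbryo(SimParams(nCellsTarget = 50L), seed = 7)
#' emb
#' @export
simulateEmbryo <- function(params = SimParams(), seed = 1L) {
  seed <- as.integer(seed)
  lat <- generateLattice(params)
  counts <- sampleCounts(lat$cells, params$genes, params$countNoise,
                         seed = seed + 101L, nbFano = params$nbFano)
  mem <- sampleMembraneSpots(lat$cells, params, seed = seed + 202L)
  rna <- sampleMrnaSpots(lat$cells, counts, params, seed = seed + 303L)
  new("SyntheticEmbryo", cells = lat$cells, trueAdjacency = lat$adjacency,
      trueCounts = counts, membraneSpots = mem, mrnaSpots = rna,
      params = unclass(params), seed = seed)
}

#' Two-colour channel counts by binomial thinning
#'
#' Emulates detecting the same transcripts with two interleaved probe sets
#' in different colours: each molecule of the parent count is detected in
#' each channel independently with probability `p`.
#'
#' @param expr a [CellExpression-class] of parent counts.
#' @param gene gene to split.
#' @param p per-channel detection probability; default 0.5.
#' @param seed integer seed.
#' @return integer matrix (cells x 2, columns `channel_a`, `channel_b`).
#' @export
twoChannelCounts <- function(expr, gene, p = 0.5, seed = 1L) {
  set.seed(seed)
  x <- countsMatrix(expr)[, gene]
  m <- cbind(channel_a = stats::rbinom(length(x), x, p),
             channel_b = stats::rbinom(length(x), x, p))
  rownames(m) <- cellIds(expr)
  m
}
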