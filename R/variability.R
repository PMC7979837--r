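## Local expression-variability statistics over immediate-neighbour groups.
##
## For a focal cell with count x and neighbour counts n_1..n_k:
##   Fano = population variance / mean of the group {x, n_1..n_k}
##          (variance and mean are population measures; all cells of the
##          group share the value when used as a moving-group statistic)
##   NV   = mean_j |x - n_j| / X_max          (X_max = population maximum
##          count of the gene over all analysed cells)
##   PV   = mean_j |x - n_j| / max{x, n_1..n_k}
## Both NV and PV range from 0 (no variability) to 1 (maximum variability).
## A lone transcript surrounded by empty neighbours scores PV = 1; the PV
## expression filter zeroes cells whose neighbour-group mean count is below
## a threshold (default 1, inclusive).

.checkCounts <- function(v, what) {
  if (length(v) && (any(!is.finite(v)) || any(v < 0) || any(v != round(v))))
    stop(what, " must be nonnegative integers")
  v
}

#' Fano factor of a neighbour group
#'
#' Population variance divided by mean of the group counts (the focal
#' cell's count together with its neighbours'). By convention 0 when the
#' mean is 0 (all-zero group). With `sample = TRUE` the n-1 denominator
#' variance is used instead.
#'
#' @param groupValues nonnegative integer counts, length >= 1.
#' @param sample use the sample (n-1) variance instead of the population
#'   variance.
#' @return nonnegative real.
#' @examples
#' fanoFactor(c(0, 0, 4))  # 8/3
#' @export
fanoFactor <- function(groupValues, sample = FALSE) {
  .checkCounts(groupValues, "group counts")
  if (!length(groupValues)) stop("group must contain at least one value")
  m <- mean(groupValues)
  if (m == 0) return(0)
  n <- length(groupValues)
  v <- sum((groupValues - m)^2) / if (sample) max(1, n - 1) else n
  v / m
}

#' Numerical variability (NV)
#'
#' Mean absolute count difference between the focal cell and each of its
#' immediate neighbours, normalised by the maximum mRNA per cell over the
#' whole cell population. High NV marks cells whose local difference is
#' numerically large relative to the gene's maximal expression. Adding a
#' constant to the focal cell and all neighbours leaves NV unchanged.
#'
#' @param x focal cell count (nonnegative integer).
#' @param neighbourValues neighbours' counts.
#' @param populationMax population-wide maximum count of the gene; must be
#'   at least the largest count involved.
#' @return value in \[0, 1\]; 0 (with a warning) for an isolated cell, and 0
#'   when `populationMax` is 0.
#' @examples
#' numericalVariability(1, rep(0, 6), 550)  # 1/550
#' @export
numericalVariability <- function(x, neighbourValues, populationMax) {
  .checkCounts(c(x, neighbourValues, populationMax), "counts")
  if (!length(neighbourValues)) {
    warning("isolated cell (no neighbours): NV set to 0")
    return(0)
  }
  if (populationMax < max(x, neighbourValues))
    stop("populationMax is smaller than an observed count")
  if (populationMax == 0) return(0)
  mean(abs(x - neighbourValues)) / populationMax
}

#' Proportional variability (PV)
#'
#' Mean absolute count difference between the focal cell and each
#' neighbour, normalised by the maximum count within the neighbour group
#' (focal cell included). High PV marks cells proportionally most different
#' from their neighbours regardless of absolute level: a cell with a single
#' mRNA surrounded by non-expressing neighbours scores the maximum PV of 1.
#'
#' @param x focal cell count.
#' @param neighbourValues neighbours' counts.
#' @return value in \[0, 1\]; 0 for an all-zero group, and 0 (with a
#'   warning) for an isolated cell.
#' @examples
#' proportionalVariability(1, rep(0, 6))   # 1
#' proportionalVariability(10, rep(5, 4))  # 0.5
#' @export
proportionalVariability <- function(x, neighbourValues) {
  .checkCounts(c(x, neighbourValues), "counts")
  if (!length(neighbourValues)) {
    warning("isolated cell (no neighbours): PV set to 0")
    return(0)
  }
  gmax <- max(x, neighbourValues)
  if (gmax == 0) return(0)
  mean(abs(x - neighbourValues)) / gmax
}

#' PV expression filter
#'
#' Retains the raw PV only for cells whose neighbour-group mean count
#' (focal cell included) reaches the threshold; cells failing the criterion
#' are assigned a score of 0. This keeps attention on variable cells inside
#' actual expression domains rather than lone transcripts outside them.
#'
#' @param pvRaw raw PV value.
#' @param groupValues focal + neighbour counts.
#' @param threshold minimum group mean (inclusive); default 1.
#' @return `pvRaw`, or 0 when the group mean is below the threshold.
#' @export
applyPvFilter <- function(pvRaw, groupValues, threshold = 1) {
  if (mean(groupValues) >= threshold) pvRaw else 0
}

#' Score every cell of an embryo
#'
#' Computes Fano, NV, raw PV and filtered PV per cell and per gene, using
#' the neighbour groups of `graph`. Per gene, the population maximum is the
#' maximum count over all cells of the table. Isolated cells (degree 0 in
#' the graph, or cells absent from the graph, e.g. excluded as degenerate
#' geometry) score 0 on all three measures and are flagged.
#'
#' @param expr a [CellExpression-class].
#' @param graph a [NeighbourGraph-class]; its cells must all be present in
#'   `expr`.
#' @param pvThreshold PV filter threshold (group mean, inclusive).
#' @param sampleVariance use the sample variance in the Fano factor.
#' @return data.frame with one row per (cell, gene): `cell_id`, `gene`,
#'   `fano`, `nv`, `pv_raw`, `pv_filtered`, `n_neighbours`, `group_mean`,
#'   `population_max`, `isolated`. Row order: gene-major, cells in table
#'   order.
#' @export
scoreEmbryo <- function(expr, graph, pvThreshold = 1,
                        sampleVariance = FALSE) {
  ids <- cellIds(expr)
  missing <- setdiff(cellIds(graph), ids)
  if (length(missing))
    stop("graph cell(s) missing from the expression table: ",
         paste(utils::head(missing, 10), collapse = ", "))
  cm <- countsMatrix(expr)
  genes <- colnames(cm)
  e <- edges(graph)
  nbList <- rep(list(character(0)), length(ids))
  names(nbList) <- ids
  if (nrow(e)) {
    nb <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
    nbList[names(nb)] <- nb
  }
  nbIdx <- lapply(nbList, match, ids)
  nNb <- lengths(nbIdx)
  out <- vector("list", length(genes))
  for (g in seq_along(genes)) {
    x <- cm[, g]
    popMax <- max(0L, x)
    fano <- nv <- pv <- pvF <- gm <- numeric(length(ids))
    for (i in seq_along(ids)) {
      if (nNb[i] == 0) { gm[i] <- x[i]; next }
      nbv <- x[nbIdx[[i]]]
      grp <- c(x[i], nbv)
      gm[i] <- mean(grp)
      fano[i] <- fanoFactor(grp, sample = sampleVariance)
      md <- mean(abs(x[i] - nbv))
      nv[i] <- if (popMax > 0) md / popMax else 0
      gmax <- max(grp)
      pv[i] <- if (gmax > 0) md / gmax else 0
      pvF[i] <- if (gm[i] >= pvThreshold) pv[i] else 0
    }
    out[[g]] <- data.frame(
      cell_id = ids, gene = genes[g], fano = fano, nv = nv, pv_raw = pv,
      pv_filtered = pvF, n_neighbours = as.integer(nNb), group_mean = gm,
      population_max = as.integer(popMax), isolated = nNb == 0,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' mRNA-count histogram
#'
#' Bins per-cell counts into intervals \[(k-1)w+1, kw\] (so with the default
#' width 5: 1-5, 6-10, ...), excluding zeros by default as in per-gene
#' count summaries of patterned genes. With `excludeZero = FALSE` zeros are
#' reported in their own `"0"` bin.
#'
#' @param values nonnegative integer counts.
#' @param binWidth bin width w (>= 1); default 5.
#' @param excludeZero drop zero counts; default TRUE.
#' @return named integer vector of bin counts, ordered by bin, including
#'   empty intermediate bins; empty when no values fall in any bin.
#' @examples
#' countHistogram(c(0, 1, 5, 6))  # 1-5: 2, 6-10: 1
#' @export
countHistogram <- function(values, binWidth = 5L, excludeZero = TRUE) {
  binWidth <- as.integer(binWidth)
  stopifnot(binWidth >= 1L)
  .checkCounts(values, "count values")
  zeros <- sum(values == 0)
  values <- values[values > 0]
  if (!length(values) && (excludeZero || zeros == 0))
    return(stats::setNames(integer(0), character(0)))
  h <- integer(0)
  if (length(values)) {
    k <- ceiling(values / binWidth)
    t <- tabulate(k, nbins = max(k))
    labels <- paste0((seq_len(max(k)) - 1L) * binWidth + 1L, "-",
                     seq_len(max(k)) * binWidth)
    h <- stats::setNames(as.integer(t), labels)
  }
  if (!excludeZero) h <- c(stats::setNames(as.integer(zeros), "0"), h)
  h
}

#' Nascent transcription ratio
#'
#' Ratio of a transcription-site intensity to the single-mRNA spot
#' intensity (use the median single-spot intensity of the embryo as the
#' denominator), an estimate of the number of nascent transcripts /
#' polymerase occupancy at the site.
#'
#' @param siteIntensity transcription-site intensity (>= 0).
#' @param singleMrnaIntensity reference single-mRNA intensity (> 0).
#' @return nonnegative ratio.
#' @export
nascentRatio <- function(siteIntensity, singleMrnaIntensity) {
  if (any(!is.finite(singleMrnaIntensity)) || any(singleMrnaIntensity <= 0))
    stop("singleMrnaIntensity must be positive")
  if (any(!is.finite(siteIntensity)) || any(siteIntensity < 0))
    stop("siteIntensity must be nonnegative")
  siteIntensity / singleMrnaIntensity
}

#' Two-channel concordance of per-cell counts
#'
#' Spearman rank correlation between two per-cell count vectors of the same
#' cells (e.g. the same gene detected with two interleaved probe sets in
#' two colours).
#'
#' @param countsA,countsB equal-length count vectors (length >= 3).
#' @return Spearman's rank correlation in \[-1, 1\]; `NA` with a warning
#'   when either vector is constant (correlation undefined).
#' @export
channelConcordance <- function(countsA, countsB) {
  if (length(countsA) != length(countsB))
    stop("count vectors must have equal length")
  if (length(countsA) < 3)
    stop("at least 3 cells are required")
  if (stats::sd(countsA) == 0 || stats::sd(countsB) == 0) {
    warning("constant count vector: rank correlation undefined")
    return(NA_real_)
  }
  stats::cor(countsA, countsB, method = "spearman")
}
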