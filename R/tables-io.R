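## CSV schemas
##
## spots:     spot_id,kind,gene,x_um,y_um,z_um,intensity,cell_id
## counts:    cell_id,centroid_x_um,centroid_y_um,centroid_z_um,<gene>,...
## adjacency: cell_a,cell_b      (unordered pairs, lexicographically sorted)
## scores:    cell_id,gene,fano,nv,pv_raw,pv_filtered,n_neighbours
##
## All files are comma-separated UTF-8 with a mandatory header row and "."
## as the decimal mark; coordinates are continuous physical micrometres.
## cell_id is an opaque string; an empty field means "unassigned" (e.g.
## basal transcripts that cannot be attributed to a cell with certainty).

.SPOT_COLS <- c("spot_id", "kind", "gene", "x_um", "y_um", "z_um",
                "intensity", "cell_id")

.readCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
}

.numericCol <- function(x, col, rows = seq_along(x)) {
  y <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(y))
  if (length(bad))
    stop("non-numeric value in column '", col, "' at data row(s) ",
         paste(utils::head(rows[bad], 5), collapse = ", "))
  y
}

#' Read a spot table
#'
#' Reads the documented spots CSV. Required columns are `spot_id`, `x_um`,
#' `y_um`, `z_um` (plus `gene` for mRNA spots); `intensity` and `cell_id`
#' are optional (`cell_id` empty = unassigned). Unknown columns are kept as
#' pass-through metadata. A `kind` column, if present, must match `kind`.
#'
#' @param path CSV file path.
#' @param kind `"membrane"` or `"mrna"`.
#' @return data.frame of spot records (one row per spot).
#' @export
readSpotTable <- function(path, kind = c("membrane", "mrna")) {
  kind <- match.arg(kind)
  df <- .readCsv(path)
  need <- c("spot_id", "x_um", "y_um", "z_um")
  if (kind == "mrna") need <- c(need, "gene")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("spot table is missing required column(s): ",
         paste(miss, collapse = ", "))
  for (cc in c("x_um", "y_um", "z_um"))
    df[[cc]] <- .numericCol(df[[cc]], cc)
  if ("intensity" %in% names(df))
    df$intensity <- .numericCol(df$intensity, "intensity")
  else
    df$intensity <- NA_real_
  if (!"cell_id" %in% names(df)) df$cell_id <- ""
  df$cell_id[is.na(df$cell_id)] <- ""
  if (!"gene" %in% names(df)) df$gene <- ""
  df$gene[is.na(df$gene)] <- ""
  if ("kind" %in% names(df)) {
    if (any(df$kind != kind))
      stop("spot table contains kind != '", kind, "'")
  } else df$kind <- kind
  validateSpotTable(df)
  df[, c(.SPOT_COLS, setdiff(names(df), .SPOT_COLS)), drop = FALSE]
}

#' Validate a spot data.frame against the schema invariants
#'
#' Checks finite coordinates, nonnegative intensities where present, and
#' that membrane spots carry no gene label.
#'
#' @param spots a spot data.frame.
#' @return the input, invisibly; errors describe the first offending rows.
#' @export
validateSpotTable <- function(spots) {
  bad <- which(!is.finite(spots$x_um) | !is.finite(spots$y_um) |
               !is.finite(spots$z_um))
  if (length(bad))
    stop("non-finite coordinates at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!is.na(spots$intensity) & spots$intensity < 0)
  if (length(bad))
    stop("negative intensity at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(spots$kind == "membrane" & spots$gene != "")
  if (length(bad))
    stop("membrane spots must have an empty gene label (row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), ")")
  invisible(spots)
}

#' Write a spot table
#'
#' @param spots spot data.frame (schema of [readSpotTable()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSpotTable <- function(spots, path) {
  validateSpotTable(spots)
  utils::write.csv(spots, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read / write a counts table
#'
#' The counts CSV has one row per cell: `cell_id`, the three centroid
#' columns, then one integer column per gene.
#'
#' @param path CSV file path.
#' @return [CellExpression-class] for the reader; `path` for the writer.
#' @export
readCountsTable <- function(path) {
  df <- .readCsv(path)
  need <- c("cell_id", "centroid_x_um", "centroid_y_um", "centroid_z_um")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("counts table is missing required column(s): ",
         paste(miss, collapse = ", "))
  genes <- setdiff(names(df), need)
  cents <- cbind(.numericCol(df$centroid_x_um, "centroid_x_um"),
                 .numericCol(df$centroid_y_um, "centroid_y_um"),
                 .numericCol(df$centroid_z_um, "centroid_z_um"))
  cm <- vapply(genes, function(g) .numericCol(df[[g]], g),
               numeric(nrow(df)))
  cm <- matrix(cm, nrow = nrow(df),
               dimnames = list(df$cell_id, genes))
  rownames(cents) <- df$cell_id
  CellExpression(cm, cents)
}

#' @rdname readCountsTable
#' @param expr a [CellExpression-class].
#' @export
writeCountsTable <- function(expr, path) {
  cm <- countsMatrix(expr)
  cents <- centroids(expr)
  df <- data.frame(cell_id = cellIds(expr),
                   centroid_x_um = cents[, 1], centroid_y_um = cents[, 2],
                   centroid_z_um = cents[, 3], check.names = FALSE)
  df <- cbind(df, as.data.frame(cm, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read / write an adjacency edge list
#'
#' The adjacency CSV holds each unordered neighbour pair once
#' (`cell_a,cell_b`, lexicographically sorted within and across rows).
#' Isolated cells do not appear in an edge list, so the reader optionally
#' takes the full cell universe.
#'
#' @param path CSV file path.
#' @param cells optional character vector of all cell ids (defaults to the
#'   ids seen in the edges).
#' @param method,parameter graph provenance to record on the object.
#' @return [NeighbourGraph-class] for the reader; `path` for the writer.
#' @export
readAdjacencyTable <- function(path, cells = NULL, method = "contact",
                               parameter = NA_real_) {
  df <- .readCsv(path)
  miss <- setdiff(c("cell_a", "cell_b"), names(df))
  if (length(miss))
    stop("adjacency table is missing required column(s): ",
         paste(miss, collapse = ", "))
  e <- as.matrix(df[, c("cell_a", "cell_b"), drop = FALSE])
  if (is.null(cells)) cells <- sort(unique(as.vector(e)))
  NeighbourGraph(cells, e, method = method, parameter = parameter)
}

#' @rdname readAdjacencyTable
#' @param graph a [NeighbourGraph-class].
#' @export
writeAdjacencyTable <- function(graph, path) {
  utils::write.csv(as.data.frame(edges(graph)), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' Read / write a variability-score table
#'
#' @param path CSV file path.
#' @return data.frame of scores for the reader; `path` for the writer.
#' @export
readScoresTable <- function(path) {
  df <- .readCsv(path)
  need <- c("cell_id", "gene", "fano", "nv", "pv_raw", "pv_filtered",
            "n_neighbours")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("scores table is missing required column(s): ",
         paste(miss, collapse = ", "))
  for (cc in c("fano", "nv", "pv_raw", "pv_filtered"))
    df[[cc]] <- .numericCol(df[[cc]], cc)
  df$n_neighbours <- as.integer(.numericCol(df$n_neighbours, "n_neighbours"))
  df
}

#' @rdname readScoresTable
#' @param scores scores data.frame (from [scoreEmbryo()]).
#' @export
writeScoresTable <- function(scores, path) {
  keep <- c("cell_id", "gene", "fano", "nv", "pv_raw", "pv_filtered",
            "n_neighbours")
  utils::write.csv(scores[, keep], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write the standard output bundle
#'
#' Writes the counts, adjacency and scores CSVs for one analysis into
#' `outdir`, after checking the three objects describe the same cells.
#'
#' @param expr [CellExpression-class].
#' @param graph [NeighbourGraph-class].
#' @param scores scores data.frame.
#' @param outdir output directory (created if needed).
#' @return character vector of the files written.
#' @export
writeOutputs <- function(expr, graph, scores, outdir) {
  ids <- cellIds(expr)
  offenders <- c(setdiff(cellIds(graph), ids), setdiff(scores$cell_id, ids))
  if (length(offenders))
    stop("cell ids absent from the counts table: ",
         paste(utils::head(unique(offenders), 10), collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- c(counts = file.path(outdir, "counts.csv"),
             adjacency = file.path(outdir, "adjacency.csv"),
             scores = file.path(outdir, "scores.csv"))
  writeCountsTable(expr, files["counts"])
  writeAdjacencyTable(graph, files["adjacency"])
  writeScoresTable(scores, files["scores"])
  files
}

#' Load a run configuration file
#'
#' Reads a flat YAML key-value file with keys `expansion_um`,
#' `expansion_fraction`, `radius_um`, `pv_group_mean_threshold`,
#' `histogram_bin_width` and `seed`; absent keys take the package defaults
#' (0.6 um expansion, PV threshold 1, bin width 5).
#'
#' @param path YAML file path.
#' @return a [RunConfig-class].
#' @export
loadConfig <- function(path) {
  cfg <- if (file.exists(path)) yaml::read_yaml(path) else
    stop("config file not found: ", path)
  if (is.null(cfg)) cfg <- list()
  known <- c("expansion_um", "expansion_fraction", "radius_um",
             "pv_group_mean_threshold", "histogram_bin_width", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    warning("ignoring unknown config key(s): ",
            paste(unknown, collapse = ", "))
  if (!is.null(cfg$expansion_um) && !is.null(cfg$expansion_fraction))
    stop("config conflict: both expansion_um and expansion_fraction are set")
  args <- list(
    pvGroupMeanThreshold = cfg$pv_group_mean_threshold %||% 1,
    histogramBinWidth = cfg$histogram_bin_width %||% 5L,
    seed = cfg$seed %||% 1L)
  if (!is.null(cfg$radius_um)) args$radiusUm <- cfg$radius_um
  if (!is.null(cfg$expansion_fraction)) {
    args$expansionFraction <- cfg$expansion_fraction
    args$expansionUm <- NA_real_
  } else if (!is.null(cfg$expansion_um)) {
    args$expansionUm <- cfg$expansion_um
  }
  do.call(RunConfig, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
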