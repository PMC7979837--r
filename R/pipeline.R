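## End-to-end pipeline: simulate (or load tables) -> polygons -> neighbours
## -> spot assignment -> per-cell counts -> variability scores -> figures,
## with a JSON manifest of per-stage outputs, content hashes, wall times and
## warnings. One global seed fans out to per-stage seeds by fixed offsets so
## each stage is reproducible in isolation.

#' Run the full analysis pipeline
#'
#' In `"synthetic"` mode a blastoderm embryo is simulated and analysed end
#' to end; ground-truth tables are written alongside with a `truth_`
#' prefix. In `"from_tables"` mode the membrane/mRNA spot CSVs (and
#' optionally a precomputed adjacency CSV) are loaded instead; a missing
#' adjacency is computed with the configured neighbour method.
#'
#' @param config a [RunConfig-class].
#' @param mode `"synthetic"` or `"from_tables"`.
#' @param outdir output directory.
#' @param simParams [SimParams()] for synthetic mode.
#' @param inputs named list of file paths for `from_tables` mode:
#'   `membrane_spots`, `mrna_spots`, optionally `adjacency`.
#' @param neighbourMethod `"contact"` (expanded-polygon intersection) or
#'   `"radius"` (centroid search with `config@radiusUm`).
#' @param render also write heatmap/histogram figures.
#' @return the manifest, invisibly (also written as `manifest.json`):
#'   config snapshot, seed, per-stage files with md5 hashes and wall times,
#'   and collected warnings (degenerate cells, unassigned/ambiguous spot
#'   fractions, isolated cells).
#' @export
runPipeline <- function(config = RunConfig(),
                        mode = c("synthetic", "from_tables"),
                        outdir, simParams = SimParams(),
                        inputs = list(),
                        neighbourMethod = c("contact", "radius"),
                        render = TRUE) {
  mode <- match.arg(mode)
  neighbourMethod <- match.arg(neighbourMethod)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outdir, "run.log")
  cat(sprintf("spotcells pipeline (%s mode, seed %d)\n", mode, config@seed),
      file = logFile)
  stages <- list()
  warningsSeen <- character(0)
  note <- function(...) {
    txt <- sprintf(...)
    message(txt)
    cat(txt, "\n", file = logFile, append = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(withCallingHandlers(expr, message = function(m) {
      cat(name, ": ", conditionMessage(m), file = logFile, append = TRUE)
      invokeRestart("muffleMessage")
    }), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stages[[name]] <<- list(elapsed_s = proc.time()[["elapsed"]] - t0)
    res
  }
  out <- function(f) file.path(outdir, f)

  cfgList <- list(expansion_um = config@expansionUm,
                  expansion_fraction = config@expansionFraction,
                  radius_um = config@radiusUm,
                  pv_group_mean_threshold = config@pvGroupMeanThreshold,
                  histogram_bin_width = config@histogramBinWidth,
                  seed = config@seed,
                  neighbour_method = neighbourMethod, mode = mode)
  note("config: %s", jsonlite::toJSON(cfgList, auto_unbox = TRUE,
                                      null = "null", na = "null"))

  if (mode == "synthetic") {
    emb <- stage("simulate", simulateEmbryo(simParams, seed = config@seed))
    membrane <- membraneSpots(emb)
    mrna <- mrnaSpots(emb)
    stage("write_inputs", {
      writeSpotTable(membrane, out("membrane_spots.csv"))
      writeSpotTable(mrna, out("mrna_spots.csv"))
      writeCountsTable(trueCounts(emb), out("truth_counts.csv"))
      writeAdjacencyTable(trueAdjacency(emb), out("truth_adjacency.csv"))
    })
  } else {
    if (is.null(inputs$membrane_spots) || is.null(inputs$mrna_spots))
      stop("from_tables mode needs inputs$membrane_spots and inputs$mrna_spots")
    membrane <- stage("read_membrane",
                      readSpotTable(inputs$membrane_spots, "membrane"))
    mrna <- stage("read_mrna", readSpotTable(inputs$mrna_spots, "mrna"))
  }

  polys <- stage("hulls", buildCellPolygons(membrane))
  if (length(degenerateCells(polys))) {
    warningsSeen <- c(warningsSeen,
                      sprintf("%d degenerate cell(s) excluded",
                              length(degenerateCells(polys))))
  }
  note("hulls: %d polygons, %d degenerate", length(polys),
       length(degenerateCells(polys)))

  graph <- if (mode == "from_tables" && !is.null(inputs$adjacency)) {
    stage("neighbours", readAdjacencyTable(inputs$adjacency,
                                           cells = cellIds(polys)))
  } else if (neighbourMethod == "contact") {
    r <- expansionDistance(config, medianCellDiameter(polys))
    stage("neighbours", detectContactNeighbours(polys, expansionUm = r))
  } else {
    if (is.na(config@radiusUm))
      stop("neighbourMethod 'radius' needs config radiusUm")
    stage("neighbours",
          detectRadiusNeighbours(centroids(polys), config@radiusUm))
  }
  note("neighbours (%s): %d edges, degree range [%d, %d]",
       graphMethod(graph), nrow(edges(graph)),
       min(neighbourCounts(graph)), max(neighbourCounts(graph)))
  stage("write_adjacency", writeAdjacencyTable(graph, out("adjacency.csv")))

  assigned <- stage("assign", assignSpotsToCells(mrna, polys))
  nUn <- sum(assigned$cell_id == "")
  nAmb <- sum(assigned$ambiguous)
  if (nUn) warningsSeen <- c(warningsSeen,
                             sprintf("%d unassigned mRNA spot(s)", nUn))
  if (nAmb) warningsSeen <- c(warningsSeen,
                              sprintf("%d ambiguous mRNA spot(s)", nAmb))
  note("assign: %d spots, %d unassigned, %d ambiguous",
       nrow(assigned), nUn, nAmb)
  stage("write_assigned",
        writeSpotTable(assigned[, setdiff(names(assigned), "ambiguous")],
                       out("mrna_spots_assigned.csv")))

  expr <- stage("counts", countsFromSpots(assigned, centroids(polys)))
  stage("write_counts", writeCountsTable(expr, out("counts.csv")))

  scores <- stage("score",
                  scoreEmbryo(expr, graph,
                              pvThreshold = config@pvGroupMeanThreshold))
  nIso <- sum(scores$isolated) / max(1, length(unique(scores$gene)))
  if (nIso) warningsSeen <- c(warningsSeen,
                              sprintf("%d isolated cell(s)", nIso))
  stage("write_scores", writeScoresTable(scores, out("scores.csv")))

  if (render) {
    stage("figures", {
      cm <- countsMatrix(expr)
      cen <- centroids(expr)
      for (g in colnames(cm)) {
        renderCellHeatmap(cm[, g], cen, out(sprintf("heatmap_counts_%s.png", g)),
                          valueLabel = paste0(g, " mRNA/cell"))
        renderCountHistogram(
          countHistogram(cm[, g], binWidth = config@histogramBinWidth),
          out(sprintf("histogram_%s.png", g)), title = g)
        sg <- scores[scores$gene == g, ]
        v <- stats::setNames(sg$pv_filtered, sg$cell_id)
        renderCellHeatmap(v, cen, out(sprintf("heatmap_pv_%s.png", g)),
                          valueLabel = paste0(g, " PV"),
                          valueRange = c(0, 1))
      }
    })
  }

  files <- list.files(outdir, pattern = "\\.(csv|png|svg)$",
                      full.names = TRUE)
  manifest <- list(
    config = cfgList,
    seed = config@seed,
    stages = lapply(stages, function(s) s["elapsed_s"]),
    warnings = warningsSeen,
    files = data.frame(
      file = basename(files),
      md5 = unname(tools::md5sum(files)),
      stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  note("done: %d files", length(files))
  invisible(manifest)
}

#' Median cell diameter of a polygon set
#'
#' Median over cells of the mean lateral (x/y) bounding-box extent - the
#' scale used to resolve a fractional polygon expansion.
#'
#' @param polygons a [CellPolygonSet-class].
#' @return diameter in micrometres.
#' @export
medianCellDiameter <- function(polygons) {
  ext <- vapply(polygons@polygons, function(p) {
    r <- apply(p$vertices[, 1:2], 2, range)
    mean(r[2, ] - r[1, ])
  }, numeric(1))
  stats::median(ext)
}
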