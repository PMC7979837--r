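## Spatial heatmaps and count histograms.
##
## A cell heatmap is one dot per cell at its projected centroid, with dot
## area and colour both increasing monotonically in the plotted value
## (counts are scaled per gene to [0, population max]; NV/PV to the fixed
## [0, 1] range).

#' @importFrom ggplot2 ggplot aes geom_point geom_col scale_size_continuous
#'   scale_colour_viridis_c coord_equal labs theme_minimal ggsave
#'   scale_x_discrete annotate ggplot_build
NULL

#' Render a per-cell spatial heatmap
#'
#' @param values named numeric vector, one value per cell (counts of one
#'   gene, or a variability score).
#' @param cellCentroids matrix of per-cell centroids in micrometres
#'   (rownames = cell ids); every cell in `values` must be present.
#' @param path output image path (`.png` or `.svg`); `NULL` to skip writing.
#' @param valueLabel legend/axis label, e.g. `"Kr mRNA/cell"` or `"NV"`.
#' @param projection `"xy"` (en face) or `"xz"` (cross-section).
#' @param valueRange colour/size normalisation range; defaults to
#'   `c(0, max(values))` (use `c(0, 1)` for NV/PV).
#' @param dotSizeRange dot size range in points (positive, increasing).
#' @param colourMap a viridis colour-map name.
#' @return the ggplot object, invisibly.
#' @export
renderCellHeatmap <- function(values, cellCentroids, path = NULL,
                              valueLabel = "value",
                              projection = c("xy", "xz"),
                              valueRange = NULL,
                              dotSizeRange = c(0.3, 2.5),
                              colourMap = "viridis") {
  projection <- match.arg(projection)
  stopifnot(length(dotSizeRange) == 2, all(dotSizeRange > 0),
            diff(dotSizeRange) > 0)
  cellCentroids <- as.matrix(cellCentroids)
  ids <- rownames(cellCentroids)
  if (is.null(names(values)) || !all(ids %in% names(values))) {
    miss <- if (is.null(names(values))) ids else setdiff(ids, names(values))
    stop("missing value for cell(s): ",
         paste(utils::head(miss, 10), collapse = ", "))
  }
  v <- values[ids]
  if (is.null(valueRange)) valueRange <- c(0, max(v, 1e-12))
  cols <- if (projection == "xy") c(1, 2) else c(1, 3)
  df <- data.frame(h = cellCentroids[, cols[1]],
                   v = cellCentroids[, cols[2]], value = as.numeric(v))
  axisLab <- if (projection == "xy") c("x (um)", "y (um)") else
    c("x (um)", "z (um)")
  p <- ggplot(df, aes(x = h, y = v, size = value, colour = value)) +
    geom_point() +
    scale_size_continuous(range = dotSizeRange, limits = valueRange) +
    scale_colour_viridis_c(limits = valueRange, option = colourMap) +
    coord_equal() +
    labs(x = axisLab[1], y = axisLab[2], size = valueLabel,
         colour = valueLabel) +
    theme_minimal()
  if (!is.null(path)) ggsave(path, p, width = 8, height = 4.5, dpi = 150)
  invisible(p)
}

#' Render an mRNA-count histogram
#'
#' Bar chart of a [countHistogram()] (bin labels "1-5", "6-10", ...). An
#' empty histogram produces an empty-axes figure with a warning rather than
#' an error.
#'
#' @param histogram named integer vector from [countHistogram()].
#' @param path output image path; `NULL` to skip writing.
#' @param title optional plot title (e.g. the gene name).
#' @return the ggplot object, invisibly.
#' @export
renderCountHistogram <- function(histogram, path = NULL, title = NULL) {
  if (!length(histogram)) {
    warning("empty histogram: rendering empty axes")
    p <- ggplot() +
      labs(x = "mRNA/cell", y = "cells", title = title) + theme_minimal()
  } else {
    df <- data.frame(bin = factor(names(histogram),
                                  levels = names(histogram)),
                     cells = as.integer(histogram))
    p <- ggplot(df, aes(x = bin, y = cells)) +
      geom_col() +
      labs(x = "mRNA/cell", y = "cells", title = title) +
      theme_minimal()
  }
  if (!is.null(path)) ggsave(path, p, width = 6, height = 4, dpi = 150)
  invisible(p)
}
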