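# Small-embryo fixtures; the full-scale defaults are exercised in the
# acceptance tests.

smallParams <- function(n = 60L, ...) SimParams(nCellsTarget = n, ...)

randomSpotTable <- function(n, kind = "mrna") {
  data.frame(
    spot_id = sprintf("s%04d", seq_len(n)),
    kind = kind,
    gene = if (kind == "mrna")
      sample(c("eve", "Kr", "hb"), n, replace = TRUE) else "",
    x_um = round(stats::runif(n, 0, 300), 6),
    y_um = round(stats::runif(n, 0, 150), 6),
    z_um = round(stats::runif(n, 0, 9.6), 6),
    intensity = ifelse(stats::runif(n) < 0.2, NA_real_,
                       round(stats::rexp(n, 0.1), 6)),
    cell_id = ifelse(stats::runif(n) < 0.1, "",
                     sprintf("cell_%03d", sample.int(99, n, replace = TRUE))),
    stringsAsFactors = FALSE)
}
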