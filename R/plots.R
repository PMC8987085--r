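#' Multi-panel overview of a pipeline run
#'
#' Top to bottom: the receptor dendrogram (optimal leaf order), tick marks
#' for known genes, the three measures along the order with their moving
#' average, and the combination score with the main peak shaded.
#'
#' @param result a [ComberonResult-class]
#' @param known genes to mark under the dendrogram
#' @return invisibly, `NULL`
#' @export
plotComberon <- function(result, known = knownAngiogenesisReceptors()) {
  ord <- result@dendrogram@order
  m <- length(ord)
  known <- intersect(toupper(known), ord)
  op <- graphics::par(mfrow = c(6, 1), mar = c(0.5, 4, 0.5, 1),
                      oma = c(3, 0, 2, 0))
  on.exit(graphics::par(op))
  graphics::plot(stats::as.dendrogram(.dendToHclust(result@dendrogram)),
                 leaflab = "none", yaxt = "n", ylab = "dendrogram")
  graphics::plot(NULL, xlim = c(1, m), ylim = c(0, 1), xaxt = "n",
                 yaxt = "n", ylab = "known", xlab = "")
  if (length(known))
    graphics::abline(v = match(known, ord), col = "red3")
  sm <- result@profile@window
  for (nm in c("fraction", "enrichment", "conservation")) {
    tr <- result@tracks[[nm]]
    v <- tr@values[ord]
    v[is.na(v)] <- 0
    graphics::plot(seq_len(m), v, type = "h", col = "grey60", xaxt = "n",
                   ylab = nm, xlab = "")
    graphics::lines(seq_len(m), movingAverage(unname(v), sm),
                    col = "darkorange", lwd = 2)
    if (length(tr@missing))
      graphics::points(match(intersect(tr@missing, ord), ord),
                       rep(0, length(intersect(tr@missing, ord))),
                       pch = 15, col = "grey80")
  }
  combo <- result@profile@combo
  graphics::plot(seq_len(m), combo, type = "l", lwd = 2, ylab = "combination",
                 xlab = "dendrogram position")
  run <- match(result@peaks@main@members, ord)
  graphics::rect(min(run), 0, max(run), max(combo), border = NA,
                 col = grDevices::adjustcolor("red", 0.15))
  graphics::lines(seq_len(m), combo, lwd = 2)
  invisible(NULL)
}

#' Heatmap of frequency correlations across studies or tissues
#'
#' Uses \pkg{pheatmap} when available, otherwise base `image()`, with the
#' rows and columns in the Ward order of [frequencyCorrelation()].
#'
#' @param freqList named list of frequency vectors or
#'   [BootstrapFrequencies-class]
#' @param ... passed to the plotting backend
#' @return invisibly, the [frequencyCorrelation()] result
#' @export
plotFrequencyHeatmap <- function(freqList, ...) {
  fc <- frequencyCorrelation(freqList)
  Rm <- fc$matrix[fc$order, fc$order]
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(Rm, cluster_rows = FALSE, cluster_cols = FALSE, ...)
  } else {
    graphics::image(seq_len(nrow(Rm)), seq_len(ncol(Rm)), Rm,
                    xlab = "", ylab = "", axes = FALSE, ...)
    graphics::axis(1, seq_len(nrow(Rm)), rownames(Rm), las = 2)
    graphics::axis(2, seq_len(ncol(Rm)), colnames(Rm), las = 2)
  }
  invisible(fc)
}

#' Ligand x receptor display heatmap with marginal profiles and hotspot box
#'
#' @param pm a [PairMatrix-class]
#' @param box optional box from [hotspotBox()]
#' @return invisibly, `NULL`
#' @export
plotPairMatrix <- function(pm, box = NULL) {
  disp <- pm@display
  disp[!pm@shown] <- NA
  op <- graphics::par(mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_along(pm@receptors), seq_along(pm@ligands), t(disp),
                  col = grDevices::hcl.colors(50, "YlOrRd", rev = TRUE),
                  xlab = "receptors (dendrogram order)",
                  ylab = "ligands (dendrogram order)")
  if (!is.null(box))
    graphics::rect(box$colRange[1] - 0.5, box$rowRange[1] - 0.5,
                   box$colRange[2] + 0.5, box$rowRange[2] + 0.5,
                   border = "blue", lwd = 2)
  invisible(NULL)
}
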