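#' @include AllClasses.R
NULL

#' Accessors for comberon classes
#'
#' Small accessor generics: `datasetSpecies` and `targetClass` return the
#' dataset labels, `cellSamples`/`cellClasses` the per-cell annotations,
#' `exprValues` the log-expression matrix, `targetCells` the ids of
#' target-class cells (optionally within one sample), `flaggedGenes` the
#' genes kept without a homolog, `networkGenes`/`networkDegree`/
#' `networkEdges` the network pieces, `leafOrder` the dendrogram leaf
#' permutation, and `frequencyValues` the named bootstrap frequencies.
#'
#' @param x an object of the matching class
#' @param sampleId optional sample id to restrict `targetCells`
#' @return the accessed component
#' @name accessors
#' @aliases datasetSpecies targetClass cellSamples cellClasses exprValues
#'   targetCells flaggedGenes networkGenes networkDegree networkEdges
#'   leafOrder frequencyValues
NULL

#' @rdname accessors
#' @export
setGeneric("datasetSpecies", function(x) standardGeneric("datasetSpecies"))
#' @rdname accessors
#' @export
setMethod("datasetSpecies", "ComberonDataset", function(x) x@species)

#' @rdname accessors
#' @export
setGeneric("targetClass", function(x) standardGeneric("targetClass"))
#' @rdname accessors
#' @export
setMethod("targetClass", "ComberonDataset", function(x) x@targetClass)

#' @rdname accessors
#' @export
setGeneric("flaggedGenes", function(x) standardGeneric("flaggedGenes"))
#' @rdname accessors
#' @export
setMethod("flaggedGenes", "ComberonDataset", function(x) x@flaggedGenes)

#' @rdname accessors
#' @export
setGeneric("cellSamples", function(x) standardGeneric("cellSamples"))
#' @rdname accessors
#' @export
setMethod("cellSamples", "ComberonDataset", function(x) {
  stats::setNames(as.character(SummarizedExperiment::colData(x)$sample),
                  colnames(x))
})

#' @rdname accessors
#' @export
setGeneric("cellClasses", function(x) standardGeneric("cellClasses"))
#' @rdname accessors
#' @export
setMethod("cellClasses", "ComberonDataset", function(x) {
  stats::setNames(as.character(SummarizedExperiment::colData(x)$cellClass),
                  colnames(x))
})

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setMethod("exprValues", "ComberonDataset", function(x) {
  SummarizedExperiment::assay(x, "logvalues")
})

#' @rdname accessors
#' @export
setGeneric("targetCells", function(x, sampleId = NULL) standardGeneric("targetCells"))
#' @rdname accessors
#' @export
setMethod("targetCells", "ComberonDataset", function(x, sampleId = NULL) {
  keep <- cellClasses(x) == x@targetClass
  if (!is.null(sampleId)) keep <- keep & cellSamples(x) %in% sampleId
  colnames(x)[keep]
})

#' @rdname accessors
#' @export
setGeneric("networkGenes", function(x) standardGeneric("networkGenes"))
#' @rdname accessors
#' @export
setMethod("networkGenes", "InteractionNetwork", function(x) names(x@degree))

#' @rdname accessors
#' @export
setGeneric("networkDegree", function(x) standardGeneric("networkDegree"))
#' @rdname accessors
#' @export
setMethod("networkDegree", "InteractionNetwork", function(x) x@degree)

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setMethod("networkEdges", "InteractionNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setGeneric("leafOrder", function(x) standardGeneric("leafOrder"))
#' @rdname accessors
#' @export
setMethod("leafOrder", "OrderedDendrogram", function(x) x@order)
#' @rdname accessors
#' @export
setMethod("leafOrder", "ComberonResult", function(x) x@dendrogram@order)

#' @rdname accessors
#' @export
setGeneric("frequencyValues", function(x) standardGeneric("frequencyValues"))
#' @rdname accessors
#' @export
setMethod("frequencyValues", "BootstrapFrequencies", function(x) x@freq)
#' @rdname accessors
#' @export
setMethod("frequencyValues", "ComberonResult", function(x) x@frequencies@freq)

setMethod("show", "ComberonDataset", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("ComberonDataset: %d genes x %d cells (%s)\n",
              nrow(object), ncol(object), object@species))
  cat(sprintf("  samples: %d | target class: '%s' (%d cells)\n",
              length(unique(cd$sample)), object@targetClass,
              sum(cd$cellClass == object@targetClass)))
  if (length(object@flaggedGenes))
    cat(sprintf("  %d genes flagged without homolog\n",
                length(object@flaggedGenes)))
})

setMethod("show", "InteractionNetwork", function(object) {
  cat(sprintf("InteractionNetwork: %d genes, %d edges\n",
              length(object@degree), nrow(object@edges)))
})

setMethod("show", "HomologMap", function(object) {
  cat(sprintf("HomologMap: %d one-to-one pairs (%s <-> %s)\n",
              length(object@a), object@speciesA, object@speciesB))
})

setMethod("show", "KnownPairList", function(object) {
  cat(sprintf("KnownPairList: %d ligand-receptor pairs\n",
              length(object@ligand)))
})

setMethod("show", "AggregatedDistance", function(object) {
  cat(sprintf("AggregatedDistance (%s): %d genes x %d receptors, %d samples\n",
              object@metric, nrow(object@M), ncol(object@M),
              length(object@provenance)))
})

setMethod("show", "OrderedDendrogram", function(object) {
  cat(sprintf("OrderedDendrogram: %d leaves, Ward linkage, optimal order\n",
              length(object@order)))
  cat("  order: ", paste(utils::head(object@order, 5L), collapse = ", "),
      if (length(object@order) > 5L) ", ..." else "", "\n", sep = "")
})

setMethod("show", "MeasureTrack", function(object) {
  cat(sprintf("MeasureTrack '%s': %d receptors (%d missing)\n",
              object@name, length(object@values), length(object@missing)))
})

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet: main peak at position %d (%d members), %d secondary\n",
              object@main@apex, length(object@main@members),
              length(object@secondary)))
})

setMethod("show", "BootstrapFrequencies", function(object) {
  cat(sprintf("BootstrapFrequencies: %d receptors over N = %d resamples\n",
              length(object@freq), object@N))
  top <- sort(object@freq, decreasing = TRUE)
  top <- top[top > 0]
  if (length(top))
    cat("  top: ", paste(sprintf("%s=%.2f", names(utils::head(top, 5L)),
                                 utils::head(top, 5L)), collapse = ", "), "\n",
        sep = "")
})

setMethod("show", "ComberonResult", function(object) {
  cat("ComberonResult\n")
  cat(sprintf("  %d receptors in dendrogram; main peak: %d members\n",
              length(object@dendrogram@order),
              length(object@peaks@main@members)))
  cat(sprintf("  bootstrap: N = %d; %d receptors with frequency > 0.5\n",
              object@frequencies@N, sum(object@frequencies@freq > 0.5)))
})

setMethod("show", "PairMatrix", function(object) {
  cat(sprintf("PairMatrix: %d ligands x %d receptors; %d cells shown\n",
              length(object@ligands), length(object@receptors),
              sum(object@shown)))
  if (!is.null(object@correlations$pearson))
    cat(sprintf("  combo vs known-pair agreement: Pearson r = %.3f\n",
                object@correlations$pearson$estimate))
})
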