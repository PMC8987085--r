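#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assays colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' ComberonDataset: annotated single-cell expression for one species
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a single
#' `logvalues` assay (genes in rows, cells in columns; log-scale normalized,
#' non-negative expression), per-cell `sample` and `cellClass` annotations in
#' `colData`, and the species label, target class and flagged (homolog-less)
#' genes as slots. Gene symbols are unique and uppercase.
#'
#' @slot species single species label, e.g. `"Homo sapiens"`.
#' @slot targetClass the `cellClass` level whose cells are analyzed
#'   (e.g. endothelial); all other cells form the contrast class.
#' @slot flaggedGenes genes retained under their original symbol because no
#'   homolog was available; treated as missing for conservation.
#' @export
setClass("ComberonDataset",
  contains = "SummarizedExperiment",
  slots = c(species = "character",
            targetClass = "character",
            flaggedGenes = "character"))

setValidity("ComberonDataset", function(object) {
  msg <- character()
  a <- SummarizedExperiment::assays(object)
  if (length(a) < 1L || !("logvalues" %in% names(a)))
    msg <- c(msg, "assay 'logvalues' is required")
  else {
    v <- a[["logvalues"]]
    if (any(!is.finite(v))) msg <- c(msg, "expression values must be finite")
    else if (any(v < 0)) msg <- c(msg, "expression values must be >= 0")
  }
  g <- rownames(object)
  if (is.null(g) || anyDuplicated(g))
    msg <- c(msg, paste("duplicate gene symbols:",
                        paste(unique(g[duplicated(g)]), collapse = ", ")))
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("sample", "cellClass") %in% colnames(cd)))
    msg <- c(msg, "colData must have columns 'sample' and 'cellClass'")
  else {
    if (anyNA(cd$sample) || anyNA(cd$cellClass))
      msg <- c(msg, "every cell needs a sample and a cell class")
    cls <- unique(as.character(cd$cellClass))
    if (length(cls) > 2L)
      msg <- c(msg, "at most two cell classes are allowed per run")
    if (length(object@targetClass) != 1L)
      msg <- c(msg, "targetClass must be a single label")
    else if (ncol(object) > 0L && !(object@targetClass %in% cls))
      msg <- c(msg, sprintf("target class '%s' not present in annotations",
                            object@targetClass))
  }
  if (length(object@species) != 1L) msg <- c(msg, "species must be length 1")
  if (length(msg)) msg else TRUE
})

#' InteractionNetwork: undirected gene-interaction network
#'
#' @slot edges two-column character matrix of unordered gene pairs, each row
#'   sorted lexicographically, no self-loops, no duplicates.
#' @slot degree named integer vector of gene degrees.
#' @export
setClass("InteractionNetwork",
  slots = c(edges = "matrix", degree = "integer"))

setValidity("InteractionNetwork", function(object) {
  e <- object@edges
  if (!is.character(e) || ncol(e) != 2L) return("edges must be a 2-column character matrix")
  if (any(e[, 1] == e[, 2])) return("self-loops are not allowed")
  if (any(e[, 1] > e[, 2])) return("edge endpoints must be sorted within rows")
  key <- paste(e[, 1], e[, 2], sep = "\r")
  if (anyDuplicated(key)) return("duplicate edges are not allowed")
  deg <- table(factor(c(e[, 1], e[, 2]), levels = names(object@degree)))
  if (!identical(as.integer(deg), unname(object@degree)))
    return("degree vector inconsistent with edges")
  TRUE
})

#' HomologMap: one-to-one homolog pairs between two species
#'
#' @slot a symbols in species A (uppercase)
#' @slot b matching symbols in species B (uppercase)
#' @slot speciesA,speciesB species labels for the two columns
#' @export
setClass("HomologMap",
  slots = c(a = "character", b = "character",
            speciesA = "character", speciesB = "character"))

setValidity("HomologMap", function(object) {
  if (length(object@a) != length(object@b)) return("a and b must align")
  if (anyDuplicated(object@a) || anyDuplicated(object@b))
    return("map must be one-to-one after resolution")
  TRUE
})

#' KnownPairList: directed ligand-receptor couples
#'
#' @slot ligand ligand gene symbols
#' @slot receptor matching receptor gene symbols
#' @export
setClass("KnownPairList", slots = c(ligand = "character", receptor = "character"))

setValidity("KnownPairList", function(object) {
  if (length(object@ligand) != length(object@receptor))
    return("ligand and receptor must align")
  if (anyDuplicated(paste(object@ligand, object@receptor, sep = "\r")))
    return("duplicate pairs are not allowed")
  TRUE
})

#' SampleDistance: per-sample gene-by-receptor distance matrix
#'
#' Rows are the genes expressed in at least `fractionCutoff` of the sample's
#' target-class cells; columns the expressed genes of interest. Entries may
#' be NA where a distance is undefined (zero-variance pair under the
#' correlation metric); those are missing values for the median aggregation.
#'
#' @slot sampleId sample identifier
#' @slot D numeric matrix, genes x receptors
#' @slot metric distance metric used
#' @export
setClass("SampleDistance",
  slots = c(sampleId = "character", D = "matrix", metric = "character"))

#' AggregatedDistance: median-aggregated gene-by-receptor distances (M)
#'
#' @slot M n x m numeric matrix, no missing values after imputation
#' @slot metric distance metric used
#' @slot provenance sample ids aggregated over (with multiplicity)
#' @export
setClass("AggregatedDistance",
  slots = c(M = "matrix", metric = "character", provenance = "character"))

setValidity("AggregatedDistance", function(object) {
  if (anyNA(object@M)) return("M must have no missing values after imputation")
  if (is.null(rownames(object@M)) || is.null(colnames(object@M)))
    return("M needs gene row names and receptor column names")
  TRUE
})

#' ResamplePlan: seeded bootstrap draws of sample ids
#'
#' @slot draws list of N character vectors, each a with-replacement draw of
#'   the k sample ids
#' @slot seed integer seed the plan was generated from
#' @export
setClass("ResamplePlan", slots = c(draws = "list", seed = "integer"))

#' ReceptorMatrix: m x m receptor distance matrix A
#'
#' Euclidean distances between the column-correlation profiles of M.
#'
#' @slot A symmetric numeric matrix with zero diagonal
#' @export
setClass("ReceptorMatrix", slots = c(A = "matrix"))

setValidity("ReceptorMatrix", function(object) {
  A <- object@A
  if (nrow(A) != ncol(A)) return("A must be square")
  if (anyNA(A)) return("A must have no missing values")
  if (max(abs(A - t(A))) > 1e-10) return("A must be symmetric within 1e-10")
  if (any(diag(A) != 0)) return("diagonal of A must be exactly 0")
  if (is.null(rownames(A))) return("A needs receptor names")
  TRUE
})

#' OrderedDendrogram: Ward linkage tree with optimal leaf order
#'
#' @slot merge,height hclust-style merge records
#' @slot labels leaf labels in the original indexing the merge records use
#' @slot order leaf order as receptor symbols (minimizing the sum of
#'   distances between adjacent leaves subject to the tree)
#' @export
setClass("OrderedDendrogram",
  slots = c(merge = "matrix", height = "numeric", labels = "character",
            order = "character"))

setValidity("OrderedDendrogram", function(object) {
  m <- length(object@order)
  if (nrow(object@merge) != m - 1L) return("merge records must number m - 1")
  if (is.unsorted(object@height)) return("heights must be non-decreasing")
  if (anyDuplicated(object@order)) return("leaf order must be a permutation")
  if (!setequal(object@order, object@labels))
    return("order must permute the leaf labels")
  TRUE
})

#' MeasureTrack: one per-receptor measure
#'
#' @slot name one of `"fraction"`, `"enrichment"`, `"conservation"`
#' @slot values named non-negative finite values, one per defined receptor
#' @slot missing receptors with undefined value (e.g. absent from the
#'   partner species); disjoint from the defined set
#' @export
setClass("MeasureTrack",
  slots = c(name = "character", values = "numeric", missing = "character"))

setValidity("MeasureTrack", function(object) {
  if (any(!is.finite(object@values))) return("values must be finite")
  if (any(object@values < 0)) return("values must be >= 0")
  if (length(intersect(names(object@values), object@missing)))
    return("missing receptors cannot also have values")
  TRUE
})

#' DEGeneSet: top differentially expressed genes with median ranks
#'
#' @slot genes gene symbols ordered by ascending median rank (at most the
#'   configured `top`, default 1000)
#' @slot medianRank named median of the per-sample ranks
#' @export
setClass("DEGeneSet", slots = c(genes = "character", medianRank = "numeric"))

#' CombinationProfile: combined, smoothed measures along the dendrogram
#'
#' @slot order receptor permutation (the dendrogram leaf order)
#' @slot combo combination score per position
#' @slot components the three normalized, smoothed tracks (named list)
#' @slot window smoothing window used
#' @export
setClass("CombinationProfile",
  slots = c(order = "character", combo = "numeric", components = "list",
            window = "integer"))

#' Peak: one detected peak of the combination score
#'
#' @slot apex position of the maximum (leftmost on ties)
#' @slot height combination score at the apex
#' @slot prominence prominence on the min-max rescaled profile
#' @slot members receptors in the contiguous half-height run around the apex
#' @export
setClass("Peak",
  slots = c(apex = "integer", height = "numeric", prominence = "numeric",
            members = "character"))

#' PeakSet: main peak plus secondary peaks
#' @slot main the highest peak
#' @slot secondary list of further peaks passing height, prominence and
#'   separation rules
#' @export
setClass("PeakSet", slots = c(main = "Peak", secondary = "list"))

#' BootstrapFrequencies: per-receptor main-peak inclusion frequencies
#' @slot freq named frequencies in [0, 1], multiples of 1/N
#' @slot N number of bootstrap resamples
#' @export
setClass("BootstrapFrequencies", slots = c(freq = "numeric", N = "integer"))

setValidity("BootstrapFrequencies", function(object) {
  f <- object@freq
  if (any(f < 0 | f > 1)) return("frequencies must lie in [0, 1]")
  if (object@N > 0 && any(abs(f * object@N - round(f * object@N)) > 1e-9))
    return("frequencies must be multiples of 1/N")
  TRUE
})

#' PermutationNull: distribution of maximum null bootstrap frequencies
#' @slot maxima per-realization maximum frequency
#' @slot R number of realizations
#' @slot N orders per realization (matching the bootstrap procedure)
#' @export
setClass("PermutationNull",
  slots = c(maxima = "numeric", R = "integer", N = "integer"))

setValidity("PermutationNull", function(object) {
  if (any(object@maxima < 0 | object@maxima > 1))
    return("maxima must lie in [0, 1]")
  TRUE
})

#' PairMatrix: ligand x receptor intercellular-communication grid
#'
#' @slot ligands,receptors axis orders (dendrogram leaf orders)
#' @slot comboMean mean of the min-max scaled combination profiles
#' @slot neighborKnown known-pair counts within dendrogram neighborhoods
#' @slot display average of `comboMean` and the rescaled `neighborKnown`
#' @slot shown logical mask, `display > 0.5` (strict)
#' @slot correlations Pearson/Spearman agreement of the two components
#' @export
setClass("PairMatrix",
  slots = c(ligands = "character", receptors = "character",
            comboMean = "matrix", neighborKnown = "matrix",
            display = "matrix", shown = "matrix", correlations = "list"))

#' ComberonResult: full single-axis pipeline output
#'
#' @slot dendrogram original-data [OrderedDendrogram]
#' @slot tracks named list of the three [MeasureTrack]s on the original data
#' @slot profile original-data [CombinationProfile]
#' @slot peaks original-data [PeakSet]
#' @slot frequencies bootstrap [BootstrapFrequencies]
#' @slot resampleOrders leaf orders per resample (for neighborhoods)
#' @slot resamplePeaks [PeakSet] per resample
#' @slot plan the [ResamplePlan] used
#' @slot config pipeline configuration snapshot
#' @export
setClass("ComberonResult",
  slots = c(dendrogram = "OrderedDendrogram", tracks = "list",
            profile = "CombinationProfile", peaks = "PeakSet",
            frequencies = "BootstrapFrequencies",
            resampleOrders = "list", resamplePeaks = "list",
            plan = "ResamplePlan", config = "list"))
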