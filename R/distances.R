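#' Per-sample gene-by-receptor distance matrix
#'
#' Computes, within one sample and over its target-class cells only, the
#' distance between every expressed gene and every expressed gene of
#' interest. A gene counts as expressed if it is non-zero in at least
#' `fractionCutoff` of the sample's target-class cells (default 5%; 1% is
#' appropriate for deeply sequenced, cell-class-enriched data). Metrics:
#'
#' * `correlation`: 1 - Pearson r of the two genes' expression vectors.
#' * `cosine`: 1 - cosine similarity.
#' * `euclidean`: Euclidean distance of the expression vectors.
#'
#' Pairs whose correlation/cosine is undefined (a zero-variance or all-zero
#' vector) get `NA` and count as missing in the median aggregation.
#'
#' @param dataset a [ComberonDataset-class]
#' @param receptors character vector of genes of interest
#' @param sampleId which sample to use
#' @param metric one of `"correlation"`, `"cosine"`, `"euclidean"`
#' @param fractionCutoff expression fraction threshold (default 0.05)
#' @param minCells minimum number of target-class cells required; below this
#'   the sample is skipped with a warning and `NULL` is returned
#' @return a [SampleDistance-class] or `NULL`
#' @export
sampleDistance <- function(dataset, receptors, sampleId,
                           metric = c("correlation", "cosine", "euclidean"),
                           fractionCutoff = 0.05, minCells = 10L) {
  metric <- match.arg(metric)
  receptors <- toupper(receptors)
  cells <- targetCells(dataset, sampleId)
  if (length(cells) < minCells) {
    warning(sprintf("sample '%s' skipped: %d target cells < minCells = %d",
                    sampleId, length(cells), minCells), call. = FALSE)
    return(NULL)
  }
  x <- exprValues(dataset)[, cells, drop = FALSE]
  frac <- rowMeans(x > 0)
  expressed <- rownames(x)[frac >= fractionCutoff]
  rec <- intersect(receptors, expressed)
  if (length(rec) == 0L) {
    warning(sprintf("sample '%s' skipped: no expressed genes of interest",
                    sampleId), call. = FALSE)
    return(NULL)
  }
  xg <- x[expressed, , drop = FALSE]
  xr <- x[rec, , drop = FALSE]
  D <- switch(metric,
    correlation = {
      suppressWarnings(r <- stats::cor(t(xg), t(xr)))
      1 - r
    },
    cosine = {
      num <- xg %*% t(xr)
      ng <- sqrt(rowSums(xg^2)); nr <- sqrt(rowSums(xr^2))
      den <- outer(ng, nr)
      s <- num / den
      s[!is.finite(s)] <- NA_real_
      1 - s
    },
    euclidean = {
      g2 <- rowSums(xg^2); r2 <- rowSums(xr^2)
      d2 <- outer(g2, r2, "+") - 2 * (xg %*% t(xr))
      sqrt(pmax(d2, 0))
    })
  dimnames(D) <- list(expressed, rec)
  new("SampleDistance", sampleId = as.character(sampleId), D = D,
      metric = metric)
}

#' Median aggregation of per-sample distance matrices
#'
#' Builds the n x m matrix `M`: rows are the union of expressed genes over
#' the samples, columns the union of expressed genes of interest, and each
#' cell is the median of the per-sample distances among non-missing values.
#' Cells missing in every sample are imputed: under the correlation or
#' cosine metric with distance 1 (no correlation); under the Euclidean
#' metric with the maximum observed entry of `M`.
#'
#' @param perSample list of [SampleDistance-class] (NULL entries allowed and
#'   ignored); repeat a sample to weight it, as bootstrap draws do
#' @param metric metric the inputs were computed with
#' @return an [AggregatedDistance-class]
#' @export
aggregateMedian <- function(perSample,
                            metric = c("correlation", "cosine", "euclidean")) {
  metric <- match.arg(metric)
  perSample <- Filter(Negate(is.null), perSample)
  if (length(perSample) < 1L) stop("need at least one sample distance matrix")
  for (sd in perSample)
    if (!identical(sd@metric, metric))
      stop("sample '", sd@sampleId, "' used metric '", sd@metric, "'")
  genes <- sort(unique(unlist(lapply(perSample, function(s) rownames(s@D)))))
  recs <- sort(unique(unlist(lapply(perSample, function(s) colnames(s@D)))))
  k <- length(perSample)
  cube <- array(NA_real_, dim = c(length(genes), length(recs), k))
  for (s in seq_len(k)) {
    D <- perSample[[s]]@D
    cube[match(rownames(D), genes), match(colnames(D), recs), s] <- D
  }
  M <- .Call_median_slices(cube)
  dimnames(M) <- list(genes, recs)
  if (anyNA(M)) {
    fill <- if (metric == "euclidean") max(M, na.rm = TRUE) else 1
    M[is.na(M)] <- fill
  }
  new("AggregatedDistance", M = M, metric = metric,
      provenance = vapply(perSample, function(s) s@sampleId, character(1)))
}

#' Seeded bootstrap resample plan
#'
#' Draws, `N` times, `k` sample ids with replacement from the dataset's
#' samples. Deterministic given the seed. Datasets with fewer than five
#' samples should be passed through [pseudoSplit()] first.
#'
#' @param dataset a [ComberonDataset-class] (or a character vector of sample
#'   ids)
#' @param N number of resamples (default 100)
#' @param seed integer seed
#' @return a [ResamplePlan-class]
#' @export
makeResamples <- function(dataset, N = 100L, seed) {
  ids <- if (is.character(dataset)) unique(dataset)
         else unique(unname(cellSamples(dataset)))
  k <- length(ids)
  if (k < 5L)
    warning("fewer than 5 samples; consider pseudoSplit() first", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  draws <- replicate(N, sample(ids, k, replace = TRUE), simplify = FALSE)
  new("ResamplePlan", draws = draws, seed = as.integer(seed))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Pool and re-split cells into pseudo-samples
#'
#' For datasets with fewer than five samples: all cells are pooled and
#' partitioned cell-wise into `nParts` disjoint pseudo-samples of near-equal
#' size so that bootstrapping is possible. Optionally stratified by cell
#' class so each part keeps the overall class ratio. Class labels are
#' preserved; sample ids are replaced by `pseudo01..`.
#'
#' @param dataset a [ComberonDataset-class]
#' @param nParts number of pseudo-samples (default 10)
#' @param seed integer seed for the random partition
#' @param stratify keep the class ratio within each part (default TRUE)
#' @param minCells per-sample target-cell requirement used to validate the
#'   split (default 10)
#' @return a re-annotated [ComberonDataset-class]
#' @export
pseudoSplit <- function(dataset, nParts = 10L, seed, stratify = TRUE,
                        minCells = 10L) {
  n <- ncol(dataset)
  nTarget <- length(targetCells(dataset))
  if (nTarget < nParts * minCells)
    stop(sprintf("cannot split: %d target cells < %d parts x %d minCells",
                 nTarget, nParts, minCells))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  part <- integer(n)
  if (stratify) {
    cls <- cellClasses(dataset)
    for (cl in unique(cls)) {
      idx <- which(cls == cl)
      part[idx] <- sample(rep_len(seq_len(nParts), length(idx)))
    }
  } else {
    part <- sample(rep_len(seq_len(nParts), n))
  }
  ids <- sprintf("pseudo%02d", part)
  ComberonDataset(exprValues(dataset), sample = ids,
                  cellClass = unname(cellClasses(dataset)),
                  targetClass = dataset@targetClass,
                  species = dataset@species,
                  flaggedGenes = dataset@flaggedGenes)
}
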