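#' The packaged set of 22 known angiogenesis receptors
#'
#' Receptors with established functional effects on angiogenesis, used as
#' an external truth set for validation; includes FLT1 and KDR, the main
#' VEGF receptors.
#'
#' @return character vector of 22 gene symbols
#' @export
knownAngiogenesisReceptors <- function() {
  c("CD36", "CD47", "CLEC14A", "CXCR2", "ENG", "FGFR1", "FGFR2", "FGFR3",
    "FLT1", "FLT4", "KDR", "KIT", "MET", "NRP1", "NRP2", "PDGFRA",
    "PDGFRB", "PLXND1", "ROBO1", "ROBO4", "TEK", "VLDLR")
}

#' Exact hypergeometric upper tail
#'
#' `P(X >= k)` for X hypergeometric: `k` or more successes when drawing
#' `n` items without replacement from a population of `N` containing `K`
#' successes.
#'
#' @param N population size
#' @param K successes in the population
#' @param n draws
#' @param k observed successes
#' @return exact tail probability
#' @export
hypergeomTail <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent counts: need 0 <= k <= min(K, n) <= N")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Permutation null of maximum bootstrap frequencies
#'
#' Null model for the significance of main-peak bootstrap frequencies when
#' the leaf order carries no co-expression information. For each of `R`
#' realizations, `N` uniformly random leaf orders are drawn (matching the
#' bootstrap procedure); per order, the combination profile is recomputed
#' from the (order-independent) normalized raw measures and the main-peak
#' members recorded; the realization's statistic is the maximum per-gene
#' inclusion frequency over the `N` orders. The distribution of these R
#' maxima estimates tail probabilities non-parametrically.
#'
#' @param tracks list of three [MeasureTrack-class]s (as from a pipeline
#'   run), or a single numeric vector of pre-summed normalized measures
#' @param R number of realizations (default 1e4; large-scale estimates in
#'   the 1e7 range need proportionally more time)
#' @param N orders per realization (default 100)
#' @param smoothWindow smoothing window of the combination (default 21)
#' @param seed integer seed
#' @return a [PermutationNull-class]
#' @export
permutationNull <- function(tracks, R = 1e4, N = 100L, smoothWindow = 21L,
                            seed = 1L) {
  v <- if (is.numeric(tracks)) tracks else {
    stopifnot(length(tracks) == 3L)
    genes <- names(tracks[[1]]@values)
    rowSums(vapply(tracks, function(t) {
      x <- t@values[genes]
      x[is.na(x)] <- 0
      .normalizeSum(unname(x))
    }, numeric(length(genes))))
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  maxima <- .Call_perm_null(as.numeric(v), as.integer(R), as.integer(N),
                            as.integer(smoothWindow))
  new("PermutationNull", maxima = maxima, R = as.integer(R),
      N = as.integer(N))
}

#' Tail probability of a permutation null
#'
#' Empirical `P(max frequency > threshold)` with a binomial (Clopper-
#' Pearson) confidence interval for the estimate.
#'
#' @param null a [PermutationNull-class]
#' @param threshold frequency threshold (e.g. 0.5)
#' @param conf confidence level for the interval (default 0.95)
#' @return list with `estimate`, `exceedances`, `R`, `conf.int`
#' @export
tailProbability <- function(null, threshold, conf = 0.95) {
  x <- sum(null@maxima > threshold)
  ci <- stats::binom.test(x, null@R, conf.level = conf)$conf.int
  list(estimate = x / null@R, exceedances = x, R = null@R,
       conf.int = as.numeric(ci))
}

#' Likelihood-ratio test of dendrogram distance to an anchor
#'
#' Tests whether known genes concentrate near an anchor receptor in the
#' optimal leaf order. Response: indicator of being a known gene (anchor
#' excluded); predictor: dendrogram distance to the anchor. The alternative
#' is a logistic regression with intercept and a linear distance term; the
#' null is intercept-only (known genes uniformly spread). The statistic is
#' twice the log-likelihood difference, with a chi-squared (1 df) survival
#' p value. Perfect separation yields a p value at the machine floor with
#' a warning.
#'
#' @param dend an [OrderedDendrogram-class]
#' @param anchor anchor receptor symbol (e.g. KDR)
#' @param known character vector of known genes
#' @return list with `statistic`, `p`, `coefficients`, `nKnown`
#' @export
lrDistanceTest <- function(dend, anchor, known) {
  known <- toupper(known)
  anchor <- toupper(anchor)
  ord <- dend@order
  if (!anchor %in% ord) stop("anchor '", anchor, "' not in dendrogram")
  rest <- setdiff(ord, anchor)
  y <- as.integer(rest %in% setdiff(known, anchor))
  if (sum(y) < 2L) stop("need at least 2 known receptors besides the anchor")
  pos <- leafPositions(dend)
  x <- abs(pos[rest] - pos[[anchor]])
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  null <- stats::glm(y ~ 1, family = stats::binomial())
  lr <- as.numeric(null$deviance - fit$deviance)
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  if (!fit$converged || any(abs(stats::coef(fit)) > 1e3)) {
    warning("possible perfect separation; p value at machine floor",
            call. = FALSE)
    p <- max(p, .Machine$double.xmin)
  }
  list(statistic = lr, p = p, coefficients = stats::coef(fit),
       nKnown = sum(y))
}

#' Compare two sets of bootstrap frequencies
#'
#' Pearson correlation over the shared receptors, overlap of the
#' above-threshold sets, and the hypergeometric upper tail of that overlap
#' within a stated receptor universe (split-half and independent-dataset
#' validation).
#'
#' @param freqsA,freqsB named frequency vectors or
#'   [BootstrapFrequencies-class]
#' @param thresholdA,thresholdB inclusion thresholds (default 0.5, strict)
#' @param population size of the common receptor universe
#' @return list with `pearson`, `nShared`, `setA`, `setB`, `overlap`,
#'   `hypergeomP`
#' @export
compareFrequencies <- function(freqsA, freqsB, thresholdA = 0.5,
                               thresholdB = 0.5, population) {
  fa <- if (is(freqsA, "BootstrapFrequencies")) freqsA@freq else freqsA
  fb <- if (is(freqsB, "BootstrapFrequencies")) freqsB@freq else freqsB
  shared <- intersect(names(fa), names(fb))
  if (length(shared) < 3L) stop("fewer than 3 shared receptors")
  r <- stats::cor(fa[shared], fb[shared])
  setA <- names(fa)[fa > thresholdA]
  setB <- names(fb)[fb > thresholdB]
  k <- length(intersect(setA, setB))
  p <- if (length(setA) && length(setB))
    hypergeomTail(population, length(setA), length(setB),
                  min(k, length(setA), length(setB)))
  else 1
  list(pearson = r, nShared = length(shared),
       setA = length(setA), setB = length(setB), overlap = k,
       hypergeomP = p)
}

#' Correlation structure of frequency sets across tissues or studies
#'
#' Pairwise Pearson correlation of bootstrap-frequency vectors (aligned on
#' the union of receptors, absent receptors counting 0), ordered by Ward
#' clustering of the Euclidean distances between correlation profiles.
#'
#' @param freqList named list of frequency vectors or
#'   [BootstrapFrequencies-class]
#' @return list with the correlation `matrix`, the display `order`, and the
#'   `hclust` tree
#' @export
frequencyCorrelation <- function(freqList) {
  if (length(freqList) < 2L) stop("need at least two frequency sets")
  fl <- lapply(freqList, function(f)
    if (is(f, "BootstrapFrequencies")) f@freq else f)
  receptors <- sort(unique(unlist(lapply(fl, names))))
  X <- vapply(fl, function(f) {
    v <- f[receptors]
    v[is.na(v)] <- 0
    unname(v)
  }, numeric(length(receptors)))
  R <- stats::cor(X)
  hc <- stats::hclust(stats::dist(R), method = "ward.D2")
  list(matrix = R, order = colnames(R)[hc$order], hclust = hc)
}

#' Combined top-receptor table across frequency sets
#'
#' Receptors in the union of (a) the global top set (receptors whose mean
#' frequency across sets exceeds `globalCutoff`) and (b) each set's top
#' `perSetTop`, as a receptor-by-set frequency matrix for heatmap display.
#'
#' @param freqList named list of frequency vectors or
#'   [BootstrapFrequencies-class]
#' @param globalCutoff mean-frequency cutoff for the global block
#' @param perSetTop per-set top count (default 10)
#' @return numeric matrix, receptors x sets
#' @export
topReceptorTable <- function(freqList, globalCutoff = 0.9, perSetTop = 10L) {
  fl <- lapply(freqList, function(f)
    if (is(f, "BootstrapFrequencies")) f@freq else f)
  receptors <- sort(unique(unlist(lapply(fl, names))))
  X <- vapply(fl, function(f) {
    v <- f[receptors]; v[is.na(v)] <- 0; unname(v)
  }, numeric(length(receptors)))
  rownames(X) <- receptors
  globalTop <- receptors[rowMeans(X) > globalCutoff]
  perSet <- unique(unlist(lapply(seq_len(ncol(X)), function(j)
    rownames(X)[utils::head(order(-X[, j]), perSetTop)])))
  sel <- union(globalTop, perSet)
  X[sel[order(-rowMeans(X[sel, , drop = FALSE]))], , drop = FALSE]
}
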