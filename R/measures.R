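#' Expression fraction of the genes of interest
#'
#' For each gene of interest and each sample: the fraction of that sample's
#' target-class cells expressing the gene at a non-zero level; fractions are
#' then aggregated across samples with the median (default) or the mean.
#' Genes absent from the dataset score 0 and are reported with a message.
#'
#' @param dataset a [ComberonDataset-class]
#' @param receptors genes of interest
#' @param aggregator `"median"` (default) or `"mean"`
#' @param sampleIds samples to use, with multiplicity (default: each sample
#'   once); bootstrap draws pass their resampled ids here
#' @param minCells samples with fewer target cells are skipped
#' @return a [MeasureTrack-class] named `"fraction"`
#' @export
expressionFraction <- function(dataset, receptors,
                               aggregator = c("median", "mean"),
                               sampleIds = NULL, minCells = 10L) {
  aggregator <- match.arg(aggregator)
  receptors <- toupper(receptors)
  per <- .perSampleFractions(dataset, receptors, minCells)
  .aggregateFractions(per, receptors, aggregator, sampleIds)
}

# per-sample expression fractions for the genes of interest; NA rows for
# genes absent from the dataset
.perSampleFractions <- function(dataset, receptors, minCells = 10L) {
  present <- intersect(receptors, rownames(dataset))
  absent <- setdiff(receptors, present)
  if (length(absent))
    message(length(absent), " gene(s) of interest absent from dataset")
  sam <- cellSamples(dataset)
  cls <- cellClasses(dataset) == dataset@targetClass
  x <- exprValues(dataset)[present, , drop = FALSE] > 0
  out <- list()
  for (s in unique(unname(sam))) {
    cells <- names(sam)[sam == s & cls]
    if (length(cells) < minCells) next
    f <- rowMeans(x[, cells, drop = FALSE])
    full <- stats::setNames(numeric(length(receptors)), receptors)
    full[present] <- f
    out[[s]] <- full
  }
  out
}

.aggregateFractions <- function(per, receptors, aggregator, sampleIds = NULL) {
  if (is.null(sampleIds)) sampleIds <- names(per)
  sampleIds <- sampleIds[sampleIds %in% names(per)]
  if (length(sampleIds) == 0L) stop("no usable samples")
  mat <- do.call(cbind, per[sampleIds])
  agg <- if (aggregator == "median") apply(mat, 1L, stats::median)
         else rowMeans(mat)
  new("MeasureTrack", name = "fraction",
      values = stats::setNames(agg, receptors), missing = character())
}

#' Top differentially expressed genes
#'
#' Per sample, a two-sided two-sample test (Welch t-test by default, or a
#' Mann-Whitney U with normal approximation) contrasts target-class against
#' other-class cells for every gene. Genes with p below `alpha` are retained
#' and ranked by decreasing test statistic (rank 1 = largest statistic). The
#' dataset-level rank of a gene is the median of its per-sample ranks over
#' the samples where it qualified; genes must qualify in at least half of
#' the usable samples. The `top` genes by ascending median rank form the set
#' S used for network enrichment.
#'
#' @param dataset a [ComberonDataset-class]
#' @param alpha per-sample p-value cutoff (default 0.001)
#' @param top maximal size of S (default 1000)
#' @param scheme `"t_test"` (Welch) or `"mann_whitney"`
#' @param sampleIds samples to use with multiplicity (default all)
#' @param minCells minimum cells per class per sample
#' @return a [DEGeneSet-class]
#' @export
differentialGenes <- function(dataset, alpha = 0.001, top = 1000L,
                              scheme = c("t_test", "mann_whitney"),
                              sampleIds = NULL, minCells = 10L) {
  scheme <- match.arg(scheme)
  per <- .perSampleDE(dataset, alpha, scheme, minCells)
  .aggregateDE(per, top = top, sampleIds = sampleIds)
}

# per sample: named vector of ranks (1 = largest statistic) of qualifying
# genes
.perSampleDE <- function(dataset, alpha = 0.001,
                         scheme = c("t_test", "mann_whitney"),
                         minCells = 10L) {
  scheme <- match.arg(scheme)
  sam <- cellSamples(dataset)
  isTarget <- cellClasses(dataset) == dataset@targetClass
  x <- exprValues(dataset)
  out <- list()
  for (s in unique(unname(sam))) {
    inS <- sam == s
    t_cells <- names(sam)[inS & isTarget]
    o_cells <- names(sam)[inS & !isTarget]
    if (length(t_cells) < minCells || length(o_cells) < minCells) next
    xt <- x[, t_cells, drop = FALSE]
    xo <- x[, o_cells, drop = FALSE]
    res <- if (scheme == "t_test") .rowWelch(xt, xo) else .rowMannWhitney(xt, xo)
    ok <- which(is.finite(res$p) & res$p < alpha)
    if (length(ok) == 0L) { out[[s]] <- stats::setNames(numeric(0), character(0)); next }
    stat <- res$stat[ok]
    ord <- order(-stat, rownames(x)[ok])
    ranks <- stats::setNames(seq_along(ord), rownames(x)[ok][ord])
    out[[s]] <- ranks
  }
  out
}

# vectorized Welch two-sample t-test per row
.rowWelch <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  stat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  list(stat = stat, p = p)
}

# vectorized Mann-Whitney U with normal approximation and tie correction;
# the standardized U (signed z) plays the role of the test statistic
.rowMannWhitney <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  x <- cbind(a, b)
  rk <- t(apply(x, 1L, rank))
  R1 <- rowSums(rk[, seq_len(na), drop = FALSE])
  U <- R1 - na * (na + 1) / 2
  mu <- na * nb / 2
  n <- na + nb
  ties <- apply(x, 1L, function(r) {
    tb <- table(r)
    sum(tb^3 - tb)
  })
  sigma2 <- na * nb / 12 * ((n + 1) - ties / (n * (n - 1)))
  z <- (U - mu) / sqrt(sigma2)
  z[!is.finite(z)] <- 0
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  list(stat = z, p = p)
}

.aggregateDE <- function(per, top = 1000L, sampleIds = NULL) {
  if (is.null(sampleIds)) sampleIds <- names(per)
  sampleIds <- sampleIds[sampleIds %in% names(per)]
  k <- length(sampleIds)
  if (k == 0L) stop("no usable samples for differential expression")
  all_genes <- unique(unlist(lapply(per[sampleIds], names)))
  if (length(all_genes) == 0L)
    stop("no gene qualifies for differential expression in any sample")
  counts <- stats::setNames(integer(length(all_genes)), all_genes)
  ranks <- matrix(NA_real_, length(all_genes), k,
                  dimnames = list(all_genes, NULL))
  for (i in seq_len(k)) {
    r <- per[[sampleIds[i]]]
    if (length(r)) {
      ranks[names(r), i] <- r
      counts[names(r)] <- counts[names(r)] + 1L
    }
  }
  qualified <- names(counts)[counts * 2L >= k]
  if (length(qualified) == 0L)
    stop("no gene qualifies in at least half of the samples")
  med <- apply(ranks[qualified, , drop = FALSE], 1L, stats::median, na.rm = TRUE)
  ord <- order(med, qualified)
  sel <- utils::head(ord, top)
  new("DEGeneSet", genes = qualified[sel],
      medianRank = stats::setNames(med[sel], qualified[sel]))
}

#' Network enrichment of connections to differentially expressed genes
#'
#' Let `p` be the fraction of network edges with at least one endpoint in
#' the DE set S. A gene of interest j with degree `n_j` and `k_j` edges to S
#' gets the binomial upper-tail probability
#' `P_j = P(X >= k_j), X ~ Binomial(n_j, p)`, and the measure is
#' `-log10 P_j`, computed in log space and capped at 320. Genes with
#' `k_j = 0` score exactly 0; genes absent from the network score 0.
#'
#' @param network an [InteractionNetwork-class]
#' @param S a [DEGeneSet-class] (or character vector of genes)
#' @param receptors genes of interest
#' @return a [MeasureTrack-class] named `"enrichment"`
#' @export
networkEnrichment <- function(network, S, receptors) {
  genes <- if (is(S, "DEGeneSet")) S@genes else toupper(S)
  if (length(genes) == 0L) stop("S is empty")
  receptors <- toupper(receptors)
  e <- network@edges
  p <- mean(e[, 1] %in% genes | e[, 2] %in% genes)
  adj <- .adjacency(network)
  vals <- stats::setNames(numeric(length(receptors)), receptors)
  for (j in receptors) {
    nbr <- adj[[j]]
    if (is.null(nbr)) next
    kj <- sum(nbr %in% genes)
    if (kj == 0L) next
    logP <- stats::pbinom(kj - 1L, length(nbr), p,
                          lower.tail = FALSE, log.p = TRUE)
    vals[j] <- min(-logP / log(10), 320)
  }
  new("MeasureTrack", name = "enrichment", values = vals,
      missing = character())
}

# neighbor lists of every gene in the network
.adjacency <- function(network) {
  e <- network@edges
  split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
}

#' Evolutionary conservation of dendrogram neighborhoods
#'
#' For each gene of interest j present in both species' orderings: the
#' number of genes in the window of (up to) `window` leaves centered at j in
#' ordering A that also occur in the same-size window centered at j's
#' position in ordering B. For an even window the extra position falls on
#' the left (positions j-25 ... j+24 for window 50), clipped at the
#' boundaries; the gene itself counts in the intersection. Genes absent
#' from either ordering (including homolog-less flagged genes) are missing.
#'
#' @param dendA,dendB [OrderedDendrogram-class] for the two species, on a
#'   shared (homolog-mapped) symbol namespace
#' @param window window size in leaves (default 50)
#' @return a [MeasureTrack-class] named `"conservation"`, with values for
#'   the genes of `dendA`
#' @export
evolutionaryConservation <- function(dendA, dendB, window = 50L) {
  ordA <- dendA@order; ordB <- dendB@order
  common <- intersect(ordA, ordB)
  missing <- setdiff(ordA, common)
  posB <- match(ordA, ordB)
  nA <- length(ordA); nB <- length(ordB)
  vals <- stats::setNames(numeric(length(common)), common)
  for (j in common) {
    pA <- match(j, ordA)
    winA <- ordA[.centeredWindow(pA, nA, window)]
    winB <- ordB[.centeredWindow(match(j, ordB), nB, window)]
    vals[j] <- length(intersect(winA, winB))
  }
  new("MeasureTrack", name = "conservation", values = vals, missing = missing)
}

#' Export a measure track as two-column TSV
#'
#' @param track a [MeasureTrack-class]
#' @param path output path; missing receptors are written as NA
#' @param order optional receptor order for the rows
#' @return invisibly, the path
#' @export
writeMeasureTrack <- function(track, path, order = NULL) {
  recs <- if (is.null(order)) c(names(track@values), track@missing) else order
  vals <- track@values[recs]
  vals[recs %in% track@missing] <- NA_real_
  utils::write.table(data.frame(receptor = recs, value = unname(vals)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
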