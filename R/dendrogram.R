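#' Receptor-by-receptor distance matrix A
#'
#' From the aggregated n x m matrix `M`, computes the m x m Pearson
#' correlation matrix `C` of M's columns and sets
#' `A[i, j] = || C[, i] - C[, j] ||_2`, the Euclidean distance between the
#' two receptors' correlation profiles. Constant columns of `M` (undefined
#' correlation) are dropped with a warning.
#'
#' @param M an [AggregatedDistance-class]
#' @return a [ReceptorMatrix-class]
#' @export
receptorMatrix <- function(M) {
  X <- M@M
  v <- colMeans(X^2) - colMeans(X)^2
  bad <- colnames(X)[!is.finite(v) | v <= 0]
  if (length(bad)) {
    warning("dropping constant column(s): ", paste(bad, collapse = ", "),
            call. = FALSE)
    X <- X[, setdiff(colnames(X), bad), drop = FALSE]
  }
  if (ncol(X) < 3L) stop("need at least 3 non-constant genes of interest")
  C <- stats::cor(X)
  G <- crossprod(C)
  d2 <- outer(diag(G), diag(G), "+") - 2 * G
  A <- sqrt(pmax(d2, 0))
  diag(A) <- 0
  A <- (A + t(A)) / 2
  dimnames(A) <- list(colnames(X), colnames(X))
  new("ReceptorMatrix", A = A)
}

#' Ward dendrogram with optimal leaf ordering
#'
#' Agglomerative clustering of `A` (treated directly as a distance matrix)
#' with Ward variance-minimization linkage, then leaf ordering minimizing
#' the sum of A-distances between adjacent leaves over all orders consistent
#' with the tree (exact dynamic program over subtree flips). Among the two
#' reversals of the optimum, the lexicographically smaller receptor sequence
#' is returned, so results are reproducible.
#'
#' @param A a [ReceptorMatrix-class]
#' @return an [OrderedDendrogram-class]
#' @export
buildDendrogram <- function(A) {
  Amat <- A@A
  hc <- stats::hclust(stats::as.dist(Amat), method = "ward.D2")
  ord <- .Call_olo_order(hc$merge, Amat)
  labels <- rownames(Amat)[ord]
  rev_labels <- rev(labels)
  if (paste(rev_labels, collapse = "\r") < paste(labels, collapse = "\r"))
    labels <- rev_labels
  new("OrderedDendrogram", merge = hc$merge, height = hc$height,
      labels = rownames(Amat), order = labels)
}

#' Dendrogram distance between two leaves
#'
#' The absolute difference of the two receptors' indices in the optimal
#' leaf order (a non-negative integer).
#'
#' @param dend an [OrderedDendrogram-class]
#' @param a,b receptor symbols
#' @return non-negative integer
#' @export
dendrogramDistance <- function(dend, a, b) {
  pos <- match(c(a, b), dend@order)
  if (anyNA(pos))
    stop("unknown receptor(s): ", paste(c(a, b)[is.na(pos)], collapse = ", "))
  abs(pos[1] - pos[2])
}

#' Leaf positions of an ordered dendrogram
#' @param dend an [OrderedDendrogram-class]
#' @return named integer vector, receptor to index
#' @export
leafPositions <- function(dend) {
  stats::setNames(seq_along(dend@order), dend@order)
}

#' Convert to hclust / export
#'
#' `asHclust` rebuilds a base-R `hclust` object (with the optimal leaf order
#' as its `order`); `exportNewick` writes the tree in Newick format via
#' \pkg{ape}; `exportDendrogramJSON` writes merge records and leaf order.
#'
#' @param dend an [OrderedDendrogram-class]
#' @return `asHclust`: an `hclust`
#' @export
asHclust <- function(dend) .dendToHclust(dend)

.dendToHclust <- function(dend) {
  structure(list(merge = dend@merge, height = dend@height,
                 order = match(dend@order, dend@labels),
                 labels = dend@labels,
                 method = "ward.D2",
                 dist.method = "euclidean-of-pearson"),
            class = "hclust")
}

#' @rdname asHclust
#' @param path output file
#' @export
exportNewick <- function(dend, path) {
  hc <- .dendToHclust(dend)
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' @rdname asHclust
#' @export
exportDendrogramJSON <- function(dend, path) {
  jsonlite::write_json(list(merge = dend@merge, height = dend@height,
                            order = dend@order),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
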