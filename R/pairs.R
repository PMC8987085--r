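#' Pairwise combination score for a ligand x receptor grid
#'
#' Both axis profiles are min-max scaled to `[0, 1]`; the pair score is the
#' mean of the two scaled values, so the matrix is the outer sum divided by
#' two.
#'
#' @param ligandProfile,receptorProfile [CombinationProfile-class] objects
#'   (or named numeric vectors already in axis order)
#' @return numeric matrix, ligands x receptors
#' @export
pairCombo <- function(ligandProfile, receptorProfile) {
  lv <- .profileVector(ligandProfile)
  rv <- .profileVector(receptorProfile)
  outer(minMaxScale(lv), minMaxScale(rv), "+") / 2
}

.profileVector <- function(p) {
  if (is(p, "CombinationProfile")) stats::setNames(p@combo, p@order)
  else if (is.numeric(p) && !is.null(names(p))) p
  else stop("need a CombinationProfile or a named numeric vector")
}

#' Bootstrap-stable dendrogram neighborhoods
#'
#' For every gene on an axis: the fraction of bootstrap resamples in which
#' another gene fell inside the window of `window` leaves centered on it.
#' Genes exceeding the presence threshold later count as that gene's
#' neighbors.
#'
#' @param resampleOrders list of leaf orders (one per resample), e.g.
#'   `result@resampleOrders`
#' @param genes gene universe for the matrix (default: union of orders)
#' @param window neighborhood window in leaves (default 50)
#' @return numeric gene x gene matrix of co-window frequencies
#' @export
neighborhoodFrequencies <- function(resampleOrders, genes = NULL,
                                    window = 50L) {
  if (length(resampleOrders) == 0L) stop("no resample orders")
  if (is.null(genes)) genes <- sort(unique(unlist(resampleOrders)))
  counts <- matrix(0L, length(genes), length(genes),
                   dimnames = list(genes, genes))
  for (ord in resampleOrders) {
    n <- length(ord)
    idx <- match(ord, genes)
    for (p in seq_len(n)) {
      g <- idx[p]
      if (is.na(g)) next
      win <- idx[.centeredWindow(p, n, window)]
      win <- win[!is.na(win)]
      counts[g, win] <- counts[g, win] + 1L
    }
  }
  counts / length(resampleOrders)
}

#' Known-pair counts within dendrogram neighborhoods
#'
#' For each grid cell (l, r): the number of known ligand-receptor pairs
#' (l', r') such that l' is a stable neighbor of l on the ligand axis and
#' r' a stable neighbor of r on the receptor axis. A gene is a stable
#' neighbor when it lies in the window in more than `presence` of the
#' bootstrap resamples (default 30%, strict).
#'
#' @param ligandNeighbors,receptorNeighbors gene x gene frequency matrices
#'   from [neighborhoodFrequencies()]
#' @param known a [KnownPairList-class]
#' @param presence resample-presence threshold (default 0.3)
#' @return integer matrix, ligands x receptors
#' @export
neighborKnownPairs <- function(ligandNeighbors, receptorNeighbors, known,
                               presence = 0.3) {
  NL <- ligandNeighbors > presence
  NR <- receptorNeighbors > presence
  lg <- colnames(NL); rg <- colnames(NR)
  P <- matrix(0L, length(lg), length(rg), dimnames = list(lg, rg))
  keep <- known@ligand %in% lg & known@receptor %in% rg
  for (i in which(keep))
    P[known@ligand[i], known@receptor[i]] <- 1L
  out <- (NL %*% P) %*% t(NR)
  storage.mode(out) <- "integer"
  out
}

#' Display matrix and component agreement of a pair grid
#'
#' The display value of a cell is the mean of the pair combination score
#' and the min-max rescaled known-pair neighborhood count; only cells with
#' display strictly above 0.5 are shown. Pearson and Spearman correlations
#' (with p values) between the two components over all cells quantify
#' their agreement; constant components give `NA`.
#'
#' @param comboMean matrix from [pairCombo()]
#' @param neighborKnown matrix from [neighborKnownPairs()], same dimnames
#' @return a [PairMatrix-class]
#' @export
pairDisplay <- function(comboMean, neighborKnown) {
  stopifnot(identical(dim(comboMean), dim(neighborKnown)))
  nk <- minMaxScale(neighborKnown)
  display <- (comboMean + nk) / 2
  shown <- display > 0.5
  cors <- list(pearson = NULL, spearman = NULL)
  if (length(comboMean) >= 3L &&
      stats::sd(comboMean) > 0 && stats::sd(neighborKnown) > 0) {
    pt <- stats::cor.test(as.numeric(comboMean), as.numeric(neighborKnown),
                          method = "pearson")
    st <- suppressWarnings(
      stats::cor.test(as.numeric(comboMean), as.numeric(neighborKnown),
                      method = "spearman"))
    cors$pearson <- list(estimate = unname(pt$estimate), p = pt$p.value)
    cors$spearman <- list(estimate = unname(st$estimate), p = st$p.value)
  }
  new("PairMatrix", ligands = rownames(comboMean),
      receptors = colnames(comboMean), comboMean = comboMean,
      neighborKnown = neighborKnown + 0, display = display, shown = shown,
      correlations = cors)
}

#' Hotspot box of a pair matrix
#'
#' Density-based clustering (DBSCAN, Euclidean on grid coordinates) of the
#' shown cells; the box is the bounding rectangle of the cluster with the
#' highest mean display value. Returns `NULL` when nothing is shown or no
#' cluster forms.
#'
#' @param pm a [PairMatrix-class]
#' @param eps DBSCAN radius in grid cells (default 3)
#' @param minPts DBSCAN core-point threshold (default 5)
#' @return list with `rowRange`, `colRange`, `ligands`, `receptors`,
#'   `meanDisplay`, or `NULL`
#' @export
hotspotBox <- function(pm, eps = 3, minPts = 5L) {
  idx <- which(pm@shown, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  cl <- .dbscan(idx, eps = eps, minPts = minPts)
  if (all(cl == 0L)) return(NULL)
  means <- vapply(setdiff(unique(cl), 0L), function(g)
    mean(pm@display[idx[cl == g, , drop = FALSE]]), numeric(1))
  best <- setdiff(unique(cl), 0L)[which.max(means)]
  pts <- idx[cl == best, , drop = FALSE]
  rr <- range(pts[, 1]); cc <- range(pts[, 2])
  list(rowRange = rr, colRange = cc,
       ligands = pm@ligands[rr[1]:rr[2]],
       receptors = pm@receptors[cc[1]:cc[2]],
       meanDisplay = max(means))
}

# plain O(n^2) DBSCAN on integer grid coordinates; 0 = noise
.dbscan <- function(pts, eps, minPts) {
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nbrs, length, integer(1)) >= minPts
  labels <- integer(n)
  cluster <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cluster <- cluster + 1L
    queue <- i
    labels[i] <- cluster
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      for (nb in nbrs[[q]]) {
        if (labels[nb] == 0L) {
          labels[nb] <- cluster
          if (core[nb]) queue <- c(queue, nb)
        }
      }
    }
  }
  labels
}

#' Two-axis intercellular-communication analysis
#'
#' Combines two single-axis pipeline results — ligands scored in one cell
#' type, receptors in another — into the pair grid: mean scaled combination
#' score, known-pair neighborhood counts from the bootstrap-stable
#' neighborhoods, display matrix with the 0.5 cutoff, component
#' correlations, and the DBSCAN hotspot box.
#'
#' @param ligandResult,receptorResult [ComberonResult-class] runs for the
#'   two axes
#' @param known a [KnownPairList-class]
#' @param window neighborhood window (default 50)
#' @param presence resample-presence threshold (default 0.3)
#' @param eps,minPts DBSCAN parameters for the hotspot box
#' @return list with `pairMatrix` ([PairMatrix-class]) and `box`
#' @export
runPairs <- function(ligandResult, receptorResult, known, window = 50L,
                     presence = 0.3, eps = 3, minPts = 5L) {
  cm <- pairCombo(ligandResult@profile, receptorResult@profile)
  nl <- neighborhoodFrequencies(ligandResult@resampleOrders,
                                genes = rownames(cm), window = window)
  nr <- neighborhoodFrequencies(receptorResult@resampleOrders,
                                genes = colnames(cm), window = window)
  nk <- neighborKnownPairs(nl, nr, known, presence = presence)
  pm <- pairDisplay(cm, nk[rownames(cm), colnames(cm)])
  list(pairMatrix = pm, box = hotspotBox(pm, eps = eps, minPts = minPts))
}

#' Export a pair matrix as long-format TSV
#'
#' Columns: ligand, receptor, comboMean, neighborKnown, display, shown.
#'
#' @param pm a [PairMatrix-class]
#' @param path output path
#' @return invisibly, the path
#' @export
writePairMatrix <- function(pm, path) {
  df <- data.frame(
    ligand = rep(pm@ligands, times = length(pm@receptors)),
    receptor = rep(pm@receptors, each = length(pm@ligands)),
    comboMean = as.numeric(pm@comboMean),
    neighborKnown = as.numeric(pm@neighborKnown),
    display = as.numeric(pm@display),
    shown = as.logical(pm@shown))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
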