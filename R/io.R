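#' Construct a ComberonDataset in memory
#'
#' @param values genes x cells numeric matrix of log-scale normalized,
#'   non-negative expression (row names = gene symbols, column names = cell
#'   ids).
#' @param sample character vector of sample ids, one per cell.
#' @param cellClass character vector of cell-class labels, one per cell
#'   (at most two distinct labels).
#' @param targetClass which class is analyzed (defaults to the first label).
#' @param species species label.
#' @param flaggedGenes genes carried without a homolog.
#' @return a [ComberonDataset-class]
#' @export
ComberonDataset <- function(values, sample, cellClass,
                            targetClass = sort(unique(cellClass))[1],
                            species = "unknown", flaggedGenes = character()) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values needs gene row names")
  if (is.null(colnames(values))) stop("values needs cell column names")
  rownames(values) <- toupper(rownames(values))
  if (length(sample) != ncol(values) || length(cellClass) != ncol(values))
    stop("sample and cellClass must have one entry per cell")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(logvalues = values),
    colData = S4Vectors::DataFrame(sample = as.character(sample),
                                   cellClass = as.character(cellClass),
                                   row.names = colnames(values)))
  new("ComberonDataset", se, species = species, targetClass = targetClass,
      flaggedGenes = toupper(flaggedGenes))
}

#' Load an expression dataset from disk
#'
#' Reads either a dense TSV/CSV (gene symbols in rows, header of cell ids)
#' or a MatrixMarket triplet file with companion gene and cell-id files, plus
#' a cell-annotation TSV with columns `cell`, `sample`, `cell_class`.
#' Orientation of MatrixMarket input is auto-detected by matching dimensions
#' against the gene/cell id files; an ambiguous square matrix is an error.
#' Gene symbols are case-folded to uppercase. Inputs may be gzip-compressed.
#'
#' The per-cell totals are expected to be constant (scaled, e.g. to 1e5,
#' then log-transformed upstream); if they differ by more than 1% relative
#' range a warning is issued, never an error, since normalization is outside
#' this pipeline.
#'
#' @param matrixPath dense matrix TSV/CSV or MatrixMarket `.mtx`.
#' @param annotationsPath TSV with columns `cell`, `sample`, `cell_class`.
#' @param genesPath,cellsPath companion one-column files for MatrixMarket
#'   input (ignored for dense input).
#' @param targetClass the analyzed class; defaults to the lexicographically
#'   first class label.
#' @param species species label.
#' @return a [ComberonDataset-class]
#' @export
loadExpression <- function(matrixPath, annotationsPath,
                           genesPath = NULL, cellsPath = NULL,
                           targetClass = NULL, species = "unknown") {
  .assertScalarString(matrixPath, "matrixPath")
  if (grepl("\\.mtx(\\.gz)?$", matrixPath)) {
    if (is.null(genesPath) || is.null(cellsPath))
      stop("MatrixMarket input requires genesPath and cellsPath")
    mm <- as.matrix(Matrix::readMM(matrixPath))
    genes <- toupper(.readTable(genesPath)[[1]])
    cells <- .readTable(cellsPath)[[1]]
    if (nrow(mm) == length(genes) && ncol(mm) == length(cells)) {
      if (nrow(mm) == ncol(mm) && length(genes) == length(cells))
        stop("ambiguous square matrix: cannot infer orientation")
    } else if (nrow(mm) == length(cells) && ncol(mm) == length(genes)) {
      mm <- t(mm)
    } else {
      stop("matrix dimensions match neither genes x cells nor cells x genes")
    }
    dimnames(mm) <- list(genes, cells)
    values <- mm
  } else {
    sep <- if (grepl("\\.csv(\\.gz)?$", matrixPath)) "," else "\t"
    tab <- utils::read.table(matrixPath, header = TRUE, sep = sep,
                             row.names = NULL, check.names = FALSE,
                             stringsAsFactors = FALSE, quote = "")
    genes <- toupper(as.character(tab[[1]]))
    values <- as.matrix(tab[, -1, drop = FALSE])
    rownames(values) <- genes
  }
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicate gene symbols: ", paste(dup, collapse = ", "))
  if (any(!is.finite(values))) stop("non-finite expression values")
  if (any(values < 0)) stop("negative expression values")

  ann <- .readAnnotations(annotationsPath)
  unknown <- setdiff(ann$cell, colnames(values))
  if (length(unknown))
    stop("annotation refers to unknown cell(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  unannotated <- setdiff(colnames(values), ann$cell)
  if (length(unannotated))
    stop("cell(s) missing annotation: ",
         paste(utils::head(unannotated, 5L), collapse = ", "))
  ann <- ann[match(colnames(values), ann$cell), ]

  sums <- colSums(values)
  if (length(sums) > 1L && max(sums) > 0 &&
      (max(sums) - min(sums)) / max(sums) > 0.01)
    warning("per-cell totals differ by more than 1%; ",
            "expected scaled, log-transformed input", call. = FALSE)

  if (is.null(targetClass)) targetClass <- sort(unique(ann$cell_class))[1]
  ComberonDataset(values, sample = ann$sample, cellClass = ann$cell_class,
                  targetClass = targetClass, species = species)
}

.readAnnotations <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           check.names = FALSE)
  need <- c("cell", "sample", "cell_class")
  if (!all(need %in% colnames(ann)))
    stop("annotations need columns: ", paste(need, collapse = ", "))
  if (length(unique(ann$cell_class)) > 2L)
    stop("annotations must contain exactly two cell classes, found: ",
         paste(unique(ann$cell_class), collapse = ", "))
  ann
}

#' Write a dataset back to the dense text dialect
#'
#' Writes the expression matrix as TSV (genes in rows, header = cell ids)
#' with full double precision, so a write/read round trip through
#' [loadExpression()] is bit-identical, plus the matching annotation TSV.
#'
#' @param x a [ComberonDataset-class]
#' @param matrixPath,annotationsPath output paths
#' @return invisibly, the two paths
#' @export
writeExpression <- function(x, matrixPath, annotationsPath) {
  v <- exprValues(x)
  con <- file(matrixPath, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(v)), collapse = "\t"), con)
  body <- apply(v, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = "\t"))
  writeLines(paste(rownames(v), body, sep = "\t"), con)
  ann <- data.frame(cell = colnames(v), sample = unname(cellSamples(x)),
                    cell_class = unname(cellClasses(x)))
  utils::write.table(ann, annotationsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrixPath, annotationsPath))
}

#' Load an undirected gene-interaction network
#'
#' Reads a two-column TSV of gene-symbol pairs (no header required; a header
#' line is tolerated and skipped if it repeats as data it is kept). Self
#' loops are dropped with a message; duplicate edges (in either orientation)
#' are collapsed.
#'
#' @param path edge-list TSV
#' @return an [InteractionNetwork-class]
#' @export
loadNetwork <- function(path) {
  tab <- tryCatch(.readTable(path), error = function(e) stop(conditionMessage(e)))
  if (nrow(tab) == 0L) stop("empty network file: ", path)
  InteractionNetwork(toupper(as.character(tab[[1]])),
                     toupper(as.character(tab[[2]])))
}

#' Construct an InteractionNetwork from endpoint vectors
#'
#' @param from,to character vectors of edge endpoints
#' @return an [InteractionNetwork-class]
#' @export
InteractionNetwork <- function(from, to) {
  from <- toupper(from); to <- toupper(to)
  loops <- from == to
  if (any(loops))
    message(sum(loops), " self-loop(s) dropped")
  from2 <- pmin(from[!loops], to[!loops])
  to2 <- pmax(from[!loops], to[!loops])
  key <- paste(from2, to2, sep = "\r")
  keep <- !duplicated(key)
  e <- cbind(from2[keep], to2[keep])
  if (nrow(e) == 0L) stop("network has no edges")
  genes <- sort(unique(c(e)))
  deg <- table(factor(c(e[, 1], e[, 2]), levels = genes))
  new("InteractionNetwork", edges = e,
      degree = stats::setNames(as.integer(deg), genes))
}

#' Load a two-species homolog map
#'
#' Reads a two-column TSV (species A symbol, species B symbol). Symbols are
#' uppercased. Many-to-many families are resolved deterministically: pairs
#' are sorted lexicographically and accepted greedily so that each symbol
#' occurs at most once; discarded pairs are reported with a message.
#'
#' @param path two-column TSV
#' @param speciesA,speciesB labels for the two columns
#' @return a [HomologMap-class]
#' @export
loadHomologs <- function(path, speciesA = "A", speciesB = "B") {
  tab <- .readTable(path)
  HomologMap(toupper(as.character(tab[[1]])), toupper(as.character(tab[[2]])),
             speciesA = speciesA, speciesB = speciesB)
}

#' Construct a HomologMap from paired symbol vectors
#' @param a,b aligned symbol vectors for the two species
#' @param speciesA,speciesB species labels
#' @return a [HomologMap-class]
#' @export
HomologMap <- function(a, b, speciesA = "A", speciesB = "B") {
  a <- toupper(a); b <- toupper(b)
  ord <- order(a, b)
  a <- a[ord]; b <- b[ord]
  keep <- logical(length(a))
  seenA <- new.env(hash = TRUE); seenB <- new.env(hash = TRUE)
  for (i in seq_along(a)) {
    if (is.null(seenA[[a[i]]]) && is.null(seenB[[b[i]]])) {
      keep[i] <- TRUE
      seenA[[a[i]]] <- TRUE; seenB[[b[i]]] <- TRUE
    }
  }
  if (any(!keep))
    message(sum(!keep), " homolog pair(s) dropped in many-to-many resolution")
  new("HomologMap", a = a[keep], b = b[keep],
      speciesA = speciesA, speciesB = speciesB)
}

#' Load known ligand-receptor pairs
#'
#' Expects a TSV with columns `ligand` and `receptor` (header optional; the
#' first two columns are used). Duplicate pairs are collapsed.
#'
#' @param path TSV path
#' @return a [KnownPairList-class]
#' @export
loadKnownPairs <- function(path) {
  first <- readLines(path, n = 1L)
  hdr <- grepl("ligand", first, ignore.case = TRUE)
  tab <- .readTable(path, header = hdr)
  KnownPairList(toupper(as.character(tab[[1]])),
                toupper(as.character(tab[[2]])))
}

#' Construct a KnownPairList
#' @param ligand,receptor aligned symbol vectors (directed ligand to receptor)
#' @return a [KnownPairList-class]
#' @export
KnownPairList <- function(ligand, receptor) {
  ligand <- toupper(ligand); receptor <- toupper(receptor)
  key <- paste(ligand, receptor, sep = "\r")
  keep <- !duplicated(key)
  new("KnownPairList", ligand = ligand[keep], receptor = receptor[keep])
}

#' Map a dataset's gene symbols onto another species' namespace
#'
#' Renames gene symbols through a one-to-one [HomologMap-class]. Genes
#' without a homolog are retained under their original symbol and flagged;
#' flagged genes count as missing for the conservation measure. Calling the
#' function again with the same target species is a no-op (idempotent).
#'
#' @param dataset a [ComberonDataset-class]
#' @param map a [HomologMap-class]
#' @param targetSpecies which namespace to map into; must match `speciesA`
#'   or `speciesB` of the map
#' @return the renamed [ComberonDataset-class]
#' @export
applyHomologs <- function(dataset, map, targetSpecies) {
  if (identical(dataset@species, targetSpecies)) return(dataset)
  if (identical(targetSpecies, map@speciesA)) {
    from <- map@b; to <- map@a
  } else if (identical(targetSpecies, map@speciesB)) {
    from <- map@a; to <- map@b
  } else {
    stop("targetSpecies '", targetSpecies, "' matches neither side of the map")
  }
  genes <- rownames(dataset)
  idx <- match(genes, from)
  renamed <- ifelse(is.na(idx), genes, to[idx])
  dup <- unique(renamed[duplicated(renamed)])
  if (length(dup))
    stop("homolog mapping creates duplicate symbols: ",
         paste(dup, collapse = ", "))
  flagged <- genes[is.na(idx)]
  v <- exprValues(dataset)
  rownames(v) <- renamed
  ComberonDataset(v, sample = unname(cellSamples(dataset)),
                  cellClass = unname(cellClasses(dataset)),
                  targetClass = dataset@targetClass,
                  species = targetSpecies, flaggedGenes = flagged)
}
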