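#' Configuration of the synthetic two-species generator
#'
#' Emulates the statistical structure the pipeline exploits: a planted
#' co-expressed receptor module in the target class (shared latent factor),
#' differentially expressed genes wired to the planted receptors in a
#' power-law interaction network, and a mirrored module in a second
#' species, plus heterogeneous per-gene baselines and dropout as in real
#' log-normalized single-cell data. Optionally plants a ligand module in
#' the contrast class with known ligand-receptor pairs joining the two
#' modules.
#'
#' @param nGenes total genes per species (receptors and ligands included)
#' @param nReceptors genes of interest on the receptor axis
#' @param nLigands genes of interest on the ligand axis (0 disables the
#'   pair layer)
#' @param nSamples samples per species
#' @param cellsPerClass cells per class per sample
#' @param plantedSize planted receptor-module size
#' @param plantedLigandSize planted ligand-module size (defaults to
#'   `plantedSize` when ligands are present)
#' @param plantedLoading latent-factor loading of planted genes
#'   (log-expression units)
#' @param noiseSd cell-level Gaussian noise on the log scale
#' @param baseMeanRange per-gene baseline mean range (uniform)
#' @param fractionBeta Beta shape parameters of the per-gene expressing
#'   fraction; the default `c(0.6, 1.6)` is right-skewed (most genes
#'   expressed in few cells, a minority in most cells), as in real
#'   log-normalized single-cell data; dropout is its complement, clipped to
#'   `[0.02, 0.98]`
#' @param plantedDropout dropout of planted genes (low, so the module is
#'   widely expressed)
#' @param nDE differentially expressed genes (up in the target class)
#' @param deEffect log-scale shift of DE genes in target cells
#' @param meanDegree average network degree (edges ~ nGenes * meanDegree/2)
#' @param degreeExponent tail exponent of the degree weights
#' @param wiredFraction fraction of DE genes each planted receptor is wired
#'   to (the enrichment signal)
#' @param strongWiredFraction fraction of genes of interest (never the
#'   planted ones) whose network neighbors are drawn entirely from the DE
#'   set, independently of everything else. Real composite networks show a
#'   handful of genes of interest whose neighborhoods saturate the
#'   upper tail of the enrichment statistic at comparable values; this
#'   marginal feature, present in both the planted and the null bundle,
#'   keeps the combination profile from being dominated by a single gene
#' @param strongWiredDegree number of DE neighbors of each strongly wired
#'   gene (equal across them, so their enrichment values tie)
#' @param conservationScramble fraction of planted receptors whose species-B
#'   copy loses the latent factor (0 = fully conserved module)
#' @param nDecoyPairs random non-planted known pairs added to the pair list
#' @return a named list with class `synthConfig`
#' @export
synthConfig <- function(nGenes = 1500L, nReceptors = 450L, nLigands = 0L,
                        nSamples = 10L, cellsPerClass = 60L,
                        plantedSize = 18L, plantedLigandSize = NULL,
                        plantedLoading = 1.0, noiseSd = 0.6,
                        baseMeanRange = c(0.5, 3), fractionBeta = c(0.25, 2),
                        plantedDropout = 0.1, nDE = 200L, deEffect = 1.5,
                        meanDegree = 6, degreeExponent = 4,
                        wiredFraction = 0.3, strongWiredFraction = 0.03,
                        strongWiredDegree = 120L,
                        conservationScramble = 0,
                        nDecoyPairs = 10L) {
  if (is.null(plantedLigandSize)) plantedLigandSize <- plantedSize
  cfg <- as.list(environment())
  nBackground <- nGenes - nReceptors - nLigands
  if (nBackground < nDE)
    stop("nGenes too small for nReceptors + nLigands + nDE")
  if (plantedSize > nReceptors) stop("plantedSize > nReceptors")
  if (nLigands > 0L && plantedLigandSize > nLigands)
    stop("plantedLigandSize > nLigands")
  class(cfg) <- "synthConfig"
  cfg
}

#' Generate a synthetic two-species bundle with planted structure
#'
#' Target-class cells express the planted receptors through a shared
#' per-cell latent factor (inducing positive pairwise correlation), DE
#' genes are up-shifted in target cells and preferentially wired to the
#' planted receptors in the network, and species B mirrors the planted
#' module through the homolog map. The returned `truth` records every
#' planted set for scoring recovery.
#'
#' @param config a [synthConfig()] list
#' @param seed integer seed; the bundle is bit-reproducible from it
#' @return list with `datasetA`, `datasetB`, `network`, `homologs`,
#'   `knownPairs`, `truth`
#' @export
generateComberonData <- function(config = synthConfig(), seed = 1L) {
  .generateBundle(config, seed, planted = TRUE)
}

#' Generate a matched null bundle with no planted structure
#'
#' Keeps the heterogeneous baselines, dropout and class differential
#' expression (so the pipeline runs), but removes the latent co-expression
#' factor, the preferential network wiring, and the cross-species module
#' alignment. Used as the control for the permutation and bootstrap nulls.
#'
#' @inheritParams generateComberonData
#' @return same bundle shape as [generateComberonData()]
#' @export
generateNullData <- function(config = synthConfig(), seed = 1L) {
  .generateBundle(config, seed, planted = FALSE)
}

.generateBundle <- function(config, seed, planted) {
  stopifnot(inherits(config, "synthConfig"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))

  receptors <- sprintf("RCP%03d", seq_len(config$nReceptors))
  ligands <- if (config$nLigands > 0L)
    sprintf("LIG%03d", seq_len(config$nLigands)) else character()
  nBack <- config$nGenes - config$nReceptors - config$nLigands
  background <- sprintf("GEN%04d", seq_len(nBack))
  genesA <- c(receptors, ligands, background)

  plantedRec <- sort(sample(receptors, config$plantedSize))
  plantedLig <- if (config$nLigands > 0L)
    sort(sample(ligands, config$plantedLigandSize)) else character()
  deGenes <- sort(sample(background, config$nDE))

  mkSpecies <- function(genes, plantedRecHere, plantedLigHere, deHere,
                        species) {
    mu <- stats::runif(length(genes), config$baseMeanRange[1],
                       config$baseMeanRange[2])
    drop <- pmin(pmax(1 - stats::rbeta(length(genes), config$fractionBeta[1],
                                       config$fractionBeta[2]),
                      0.02), 0.98)
    names(mu) <- names(drop) <- genes
    mu[c(plantedRecHere, plantedLigHere)] <- 2.5
    drop[c(plantedRecHere, plantedLigHere)] <- config$plantedDropout
    # detectably differential genes are well expressed, as in real data
    drop[deHere] <- pmin(drop[deHere], 0.15)
    nCells <- 2L * config$cellsPerClass * config$nSamples
    vals <- matrix(0, length(genes), nCells)
    rownames(vals) <- genes
    cellNames <- character(nCells)
    sampleIds <- character(nCells)
    classes <- character(nCells)
    col <- 0L
    for (s in seq_len(config$nSamples)) {
      for (cl in c("target", "other")) {
        nc <- config$cellsPerClass
        cols <- col + seq_len(nc)
        x <- matrix(stats::rnorm(length(genes) * nc, mean = mu,
                                 sd = config$noiseSd),
                    length(genes), nc, dimnames = list(genes, NULL))
        if (cl == "target") {
          x[deHere, ] <- x[deHere, ] + config$deEffect
          if (length(plantedRecHere)) {
            f <- stats::rnorm(nc)
            x[plantedRecHere, ] <- x[plantedRecHere, ] +
              config$plantedLoading * rep(f, each = length(plantedRecHere))
          }
        } else if (length(plantedLigHere)) {
          f <- stats::rnorm(nc)
          x[plantedLigHere, ] <- x[plantedLigHere, ] +
            config$plantedLoading * rep(f, each = length(plantedLigHere))
        }
        keep <- matrix(stats::runif(length(genes) * nc) >= drop,
                       length(genes), nc)
        x <- pmax(x, 0) * keep
        vals[, cols] <- x
        cellNames[cols] <- sprintf("%s_s%02d_%s_%03d", species, s, cl,
                                   seq_len(nc))
        sampleIds[cols] <- sprintf("s%02d", s)
        classes[cols] <- cl
        col <- col + nc
      }
    }
    colnames(vals) <- cellNames
    ComberonDataset(vals, sample = sampleIds, cellClass = classes,
                    targetClass = "target", species = species)
  }

  pr <- if (planted) plantedRec else character()
  pl <- if (planted) plantedLig else character()
  datasetA <- mkSpecies(genesA, pr, pl, deGenes, "speciesA")

  # species B lives in its own namespace, joined by the homolog map
  genesB <- paste0(genesA, "B")
  map <- HomologMap(genesA, genesB, speciesA = "speciesA",
                    speciesB = "speciesB")
  toB <- function(x) if (length(x)) paste0(x, "B") else character()
  prB <- if (planted) {
    nScr <- round(config$conservationScramble * length(plantedRec))
    toB(setdiff(plantedRec, sample(plantedRec, nScr)))
  } else character()
  plB <- if (planted) toB(plantedLig) else character()
  datasetB <- mkSpecies(genesB, prB, plB, toB(deGenes), "speciesB")

  network <- .synthNetwork(genesA, deGenes, if (planted) plantedRec else
    character(), c(receptors, ligands), config)

  knownPairs <- .synthKnownPairs(plantedLig, plantedRec, ligands, receptors,
                                 config, planted)

  list(datasetA = datasetA, datasetB = datasetB, network = network,
       homologs = map, knownPairs = knownPairs,
       truth = list(plantedReceptors = if (planted) plantedRec else character(),
                    plantedLigands = if (planted) plantedLig else character(),
                    deGenes = deGenes,
                    receptors = receptors, ligands = ligands,
                    planted = planted, seed = as.integer(seed),
                    config = config))
}

# power-law-weighted random edges plus (when planted) wiring of each
# planted receptor to a fixed fraction of the DE genes
.synthNetwork <- function(genes, deGenes, plantedRec, interest, config) {
  n <- length(genes)
  nEdges <- round(n * config$meanDegree / 2)
  w <- (seq_len(n) / n)^(-1 / (config$degreeExponent - 1))
  w <- w / sum(w)
  w <- w[sample.int(n)] # detach weight rank from gene order
  from <- sample(genes, 2L * nEdges, replace = TRUE, prob = w)
  to <- sample(genes, 2L * nEdges, replace = TRUE, prob = w)
  keep <- from != to
  from <- from[keep][seq_len(min(nEdges, sum(keep)))]
  to <- to[keep][seq_len(length(from))]
  # a few strongly wired genes of interest whose neighborhoods are all DE:
  # their enrichment values tie exactly (same degree, same DE count)
  pool <- setdiff(interest, plantedRec)
  strong <- sample(pool, min(length(pool),
                             round(config$strongWiredFraction *
                                   length(interest))))
  if (length(strong)) {
    keep2 <- !(from %in% strong | to %in% strong)
    from <- from[keep2]; to <- to[keep2]
    nW <- min(config$strongWiredDegree, length(deGenes))
    for (r in strong) {
      tgt <- sample(deGenes, nW)
      from <- c(from, rep(r, nW))
      to <- c(to, tgt)
    }
  }
  if (length(plantedRec)) {
    nW <- round(config$wiredFraction * length(deGenes))
    for (r in plantedRec) {
      tgt <- sample(deGenes, nW)
      from <- c(from, rep(r, nW))
      to <- c(to, tgt)
    }
  }
  suppressMessages(InteractionNetwork(from, to))
}

.synthKnownPairs <- function(plantedLig, plantedRec, ligands, receptors,
                             config, planted) {
  lg <- character(); rc <- character()
  if (planted && length(plantedLig)) {
    k <- max(length(plantedLig), length(plantedRec))
    lg <- rep_len(plantedLig, k)
    rc <- rep_len(plantedRec, k)
  }
  if (config$nDecoyPairs > 0L && length(ligands)) {
    lg <- c(lg, sample(setdiff(ligands, plantedLig), config$nDecoyPairs,
                       replace = TRUE))
    rc <- c(rc, sample(setdiff(receptors, plantedRec), config$nDecoyPairs,
                       replace = TRUE))
  }
  if (length(lg) == 0L)
    return(new("KnownPairList", ligand = character(), receptor = character()))
  KnownPairList(lg, rc)
}

#' Materialize a small fixture bundle on disk
#'
#' Writes a generated bundle in the exact text formats the loaders read:
#' dense expression TSVs with annotation files for both species, the
#' network edge list, the homolog map, the known-pair list, and a
#' `truth.json`.
#'
#' @param dir output directory
#' @param config a [synthConfig()]; the default fixture is deliberately
#'   small
#' @param seed integer seed
#' @param null generate the matched null bundle instead
#' @return invisibly, the directory
#' @export
writeFixtures <- function(dir,
                          config = synthConfig(nGenes = 200L,
                                               nReceptors = 40L,
                                               nSamples = 5L,
                                               cellsPerClass = 30L,
                                               plantedSize = 8L, nDE = 40L),
                          seed = 1L, null = FALSE) {
  bundle <- if (null) generateNullData(config, seed)
            else generateComberonData(config, seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeExpression(bundle$datasetA, file.path(dir, "expressionA.tsv"),
                  file.path(dir, "annotationsA.tsv"))
  writeExpression(bundle$datasetB, file.path(dir, "expressionB.tsv"),
                  file.path(dir, "annotationsB.tsv"))
  utils::write.table(bundle$network@edges, file.path(dir, "network.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(cbind(bundle$homologs@a, bundle$homologs@b),
                     file.path(dir, "homologs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(ligand = bundle$knownPairs@ligand,
                                receptor = bundle$knownPairs@receptor),
                     file.path(dir, "known_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$truth[c("plantedReceptors", "plantedLigands",
                                      "deGenes", "receptors", "ligands",
                                      "planted", "seed")],
                       file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
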