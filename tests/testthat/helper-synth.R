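# small generator configurations and shared fixtures for the test suite

smallConfig <- function(...) {
  synthConfig(nGenes = 400L, nReceptors = 80L, nSamples = 5L,
              cellsPerClass = 30L, plantedSize = 8L, nDE = 60L,
              strongWiredDegree = 40L, ...)
}

# one small planted bundle and its pipeline run, generated once per session
.fixtures <- new.env(parent = emptyenv())

smallBundle <- function() {
  if (is.null(.fixtures$bundle))
    .fixtures$bundle <- generateComberonData(smallConfig(), seed = 7)
  .fixtures$bundle
}

smallRun <- function() {
  if (is.null(.fixtures$run)) {
    b <- smallBundle()
    .fixtures$run <- runComberon(b$datasetA, b$truth$receptors, b$network,
                                 partner = b$datasetB, homologs = b$homologs,
                                 config = comberonConfig(), seed = 11)
  }
  .fixtures$run
}

# hand-built dataset: values given explicitly, one or more samples
makeDataset <- function(values, sample, cellClass, targetClass = "target",
                        species = "speciesA") {
  ComberonDataset(values, sample = sample, cellClass = cellClass,
                  targetClass = targetClass, species = species)
}

# a valid chain-shaped OrderedDendrogram with the given leaf order; used
# where only positions matter
fakeDend <- function(order) {
  m <- length(order)
  stopifnot(m >= 2)
  merge <- matrix(0L, m - 1L, 2L)
  merge[1L, ] <- c(-1L, -2L)
  if (m > 2L) for (i in 2L:(m - 1L)) merge[i, ] <- c(i - 1L, -(i + 1L))
  new("OrderedDendrogram", merge = merge, height = seq_len(m - 1L) * 1.0,
      labels = order, order = order)
}

# exhaustive optimum of the adjacent-distance sum over all leaf orders
# consistent with an hclust-style merge matrix (flip enumeration)
bruteForceLeafOrders <- function(merge) {
  expand <- function(code) {
    if (code < 0) return(list(-code))
    left <- expand(merge[code, 1]); right <- expand(merge[code, 2])
    out <- list()
    for (l in left) for (r in right) {
      out[[length(out) + 1L]] <- c(l, r)
      out[[length(out) + 1L]] <- c(r, l)
    }
    out
  }
  unique(expand(nrow(merge)))
}

adjacentSum <- function(order, D) {
  sum(D[cbind(order[-length(order)], order[-1])])
}
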