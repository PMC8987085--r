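test_that("expression fraction aggregates per-sample fractions", {
  # 3 samples of 10 target cells; receptor nonzero in 2, 4, 6 cells
  nz <- c(2, 4, 6)
  v <- do.call(cbind, lapply(1:3, function(s)
    matrix(c(rep(1, nz[s]), rep(0, 10 - nz[s]), rep(1, 10)), 2, 10,
           byrow = TRUE)))
  rownames(v) <- c("RCP", "ALWAYS")
  colnames(v) <- paste0("c", 1:30)
  ds <- makeDataset(v, sample = rep(paste0("s", 1:3), each = 10),
                    cellClass = rep("target", 30))
  tr <- expressionFraction(ds, c("RCP", "ALWAYS"), minCells = 5)
  expect_equal(unname(tr@values["RCP"]), 0.4)      # median of .2 .4 .6
  expect_equal(unname(tr@values["ALWAYS"]), 1)
  trm <- expressionFraction(ds, "RCP", aggregator = "mean", minCells = 5)
  expect_equal(unname(trm@values["RCP"]), 0.4)

  # aggregator switch matters for skewed fractions {0, 0, 0.9}
  nz2 <- c(0, 0, 9)
  v2 <- do.call(cbind, lapply(1:3, function(s)
    matrix(c(rep(1, nz2[s]), rep(0, 10 - nz2[s])), 1, 10)))
  rownames(v2) <- "SKEW"; colnames(v2) <- paste0("c", 1:30)
  ds2 <- makeDataset(v2, sample = rep(paste0("s", 1:3), each = 10),
                     cellClass = rep("target", 30))
  expect_equal(unname(expressionFraction(ds2, "SKEW", minCells = 5)@values), 0)
  expect_equal(unname(expressionFraction(ds2, "SKEW", aggregator = "mean",
                                         minCells = 5)@values), 0.3)

  # absent receptor scores zero and is logged
  expect_message(tr0 <- expressionFraction(ds, c("RCP", "GHOST"),
                                           minCells = 5), "absent")
  expect_equal(unname(tr0@values["GHOST"]), 0)
})

test_that("median DE ranks aggregate across qualifying samples", {
  per <- list(s1 = c(GA = 1, GB = 2), s2 = c(GB = 5, GA = 1),
              s3 = c(GB = 8, GC = 1))
  out <- comberon:::.aggregateDE(per, top = 10)
  expect_equal(unname(out@medianRank["GB"]), 5)  # median of 2, 5, 8
  expect_equal(unname(out@medianRank["GA"]), 1)
  # GC qualified in 1 of 3 samples only: excluded by the half rule
  expect_false("GC" %in% out@genes)
  expect_identical(out@genes[1], "GA")
})

test_that("planted DE genes dominate the top of the DE set", {
  b <- smallBundle()
  S <- differentialGenes(b$datasetA, top = length(b$truth$deGenes))
  hit <- mean(S@genes %in% b$truth$deGenes)
  expect_gte(hit, 0.95)
  # the Mann-Whitney scheme finds essentially the same genes
  S2 <- differentialGenes(b$datasetA, top = length(b$truth$deGenes),
                          scheme = "mann_whitney")
  expect_gte(mean(S2@genes %in% b$truth$deGenes), 0.9)
})

test_that("network enrichment reproduces hand-computed binomial tails", {
  # receptor RCP with both edges into S; 2 of 4 edges touch S -> p = 0.5
  net <- InteractionNetwork(c("RCP", "RCP", "X1", "X3"),
                            c("S1", "S2", "X2", "X4"))
  tr <- networkEnrichment(net, c("S1", "S2"), "RCP")
  expect_equal(unname(tr@values["RCP"]), -log10(0.25), tolerance = 1e-9)

  # n_j = 3, k_j = 2, p = 0.1: 20 edges, 2 touching S
  from <- c("RCP", "RCP", "RCP", paste0("A", 1:17))
  to <- c("S1", "S2", "X0", paste0("B", 1:17))
  net2 <- InteractionNetwork(from, to)
  tr2 <- networkEnrichment(net2, c("S1", "S2"), "RCP")
  expect_equal(unname(tr2@values["RCP"]),
               -log10(1 - 0.729 - 0.243), tolerance = 1e-6)

  # k_j = 0 and genes absent from the network score exactly zero
  tr3 <- networkEnrichment(net2, "S9", c("RCP", "NOWHERE"))
  expect_identical(unname(tr3@values), c(0, 0))
})

test_that("binomial enrichment matches exhaustive enumeration for small degrees", {
  # oracle: sum the binomial pmf over i = k..n by explicit enumeration
  enumTail <- function(n, k, p)
    sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i),
               numeric(1)))
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(1:12, 1); k <- sample(seq_len(n), 1); p <- runif(1, 0.05, 0.9)
    expect_equal(pbinom(k - 1, n, p, lower.tail = FALSE), enumTail(n, k, p),
                 tolerance = 1e-12)
  }
  # and through the public surface: random small network against the oracle
  set.seed(22)
  genes <- paste0("G", 1:30)
  from <- sample(genes, 60, replace = TRUE)
  to <- sample(genes, 60, replace = TRUE)
  net <- suppressMessages(InteractionNetwork(from, to))
  S <- sample(genes, 8)
  recs <- intersect(networkGenes(net), genes[1:10])
  tr <- networkEnrichment(net, S, recs)
  e <- networkEdges(net)
  p <- mean(e[, 1] %in% S | e[, 2] %in% S)
  for (r in recs) {
    nbr <- c(e[e[, 1] == r, 2], e[e[, 2] == r, 1])
    k <- sum(nbr %in% S)
    want <- if (k == 0) 0 else -log10(enumTail(length(nbr), k, p))
    expect_equal(unname(tr@values[r]), want, tolerance = 1e-9)
  }
})

test_that("conservation counts window overlaps between species", {
  labs <- paste0("R", sprintf("%03d", 1:200))
  dA <- fakeDend(labs)
  # identical orderings: interior receptors overlap fully (window 50)
  trSame <- evolutionaryConservation(dA, fakeDend(labs), window = 50)
  expect_equal(unname(trSame@values["R100"]), 50)
  # boundary windows are clipped
  expect_equal(unname(trSame@values["R001"]), 25)

  # disjoint receptor universes: everything missing
  trNone <- evolutionaryConservation(dA, fakeDend(paste0("Q", 1:50)))
  expect_identical(length(trNone@values), 0L)
  expect_setequal(trNone@missing, labs)

  # reversed ordering: the asymmetric 25/24 window loses one position,
  # checked against an explicit set oracle
  dB <- fakeDend(rev(labs))
  trRev <- evolutionaryConservation(dA, dB, window = 50)
  oracle <- function(j) {
    pA <- match(j, labs); pB <- match(j, rev(labs))
    wA <- labs[max(1, pA - 25):min(200, pA + 24)]
    wB <- rev(labs)[max(1, pB - 25):min(200, pB + 24)]
    length(intersect(wA, wB))
  }
  for (j in c("R100", "R050", "R150"))
    expect_equal(unname(trRev@values[j]), oracle(j))
  expect_equal(unname(trRev@values["R100"]), 49)

  # symmetry for interior positions
  trBA <- evolutionaryConservation(dB, dA, window = 50)
  expect_equal(unname(trRev@values["R100"]), unname(trBA@values["R100"]))
})

test_that("measure tracks are invariant to cell and sample order", {
  b <- smallBundle()
  ds <- b$datasetA
  set.seed(30)
  perm <- sample(ncol(ds))
  shuffled <- ComberonDataset(exprValues(ds)[, perm],
                              sample = unname(cellSamples(ds))[perm],
                              cellClass = unname(cellClasses(ds))[perm],
                              targetClass = "target",
                              species = datasetSpecies(ds))
  recs <- b$truth$receptors[1:20]
  t1 <- expressionFraction(ds, recs)
  t2 <- expressionFraction(shuffled, recs)
  expect_equal(t1@values, t2@values)
  s1 <- differentialGenes(ds, top = 50)
  s2 <- differentialGenes(shuffled, top = 50)
  expect_identical(s1@genes, s2@genes)
})
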