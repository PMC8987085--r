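test_that("generation is bit-reproducible from the seed", {
  b1 <- generateComberonData(smallConfig(), seed = 3)
  b2 <- generateComberonData(smallConfig(), seed = 3)
  expect_identical(exprValues(b1$datasetA), exprValues(b2$datasetA))
  expect_identical(b1$network@edges, b2$network@edges)
  expect_identical(b1$truth$plantedReceptors, b2$truth$plantedReceptors)
  b3 <- generateComberonData(smallConfig(), seed = 4)
  expect_false(identical(exprValues(b1$datasetA), exprValues(b3$datasetA)))
})

test_that("the planted module is co-expressed in target cells", {
  b <- generateComberonData(synthConfig(), seed = 7)
  x <- exprValues(b$datasetA)[b$truth$plantedReceptors,
                              targetCells(b$datasetA)]
  cm <- cor(t(x))
  expect_gte(mean(cm[upper.tri(cm)]), 0.4)
  # and not in the contrast cells (no latent factor there)
  other <- setdiff(colnames(b$datasetA), targetCells(b$datasetA))
  cmO <- cor(t(exprValues(b$datasetA)[b$truth$plantedReceptors, other]))
  expect_lt(mean(cmO[upper.tri(cmO)]), 0.1)
})

test_that("full dropout forces a zero expression fraction", {
  b <- generateComberonData(smallConfig(plantedDropout = 1), seed = 2)
  tr <- suppressMessages(
    expressionFraction(b$datasetA, b$truth$plantedReceptors, minCells = 5))
  expect_true(all(tr@values == 0))
})

test_that("planted structure carries through to the measures", {
  b <- smallBundle()
  res <- smallRun()
  pl <- b$truth$plantedReceptors
  # enrichment: planted receptors dominate the background
  enr <- res@tracks$enrichment@values
  expect_gt(min(enr[intersect(pl, names(enr))]),
            median(enr[setdiff(names(enr), pl)]))
  # conservation, with a window matched to the small axis: the aligned
  # module beats the background (the default window of 50 spans most of an
  # 80-leaf axis and carries no signal there)
  cfg <- comberonConfig()
  pd <- applyHomologs(b$datasetB, b$homologs, "speciesA")
  st <- comberon:::.prepareAxis(pd, b$truth$receptors, cfg, 1)
  dendB <- buildDendrogram(receptorMatrix(
    aggregateMedian(st$dists, metric = "correlation")))
  cons <- evolutionaryConservation(res@dendrogram, dendB, window = 10)
  plIn <- intersect(pl, names(cons@values))
  expect_gt(mean(cons@values[plIn]),
            mean(cons@values[setdiff(names(cons@values), pl)]))
})

test_that("planted receptors top the bootstrap frequency ranking", {
  b <- smallBundle()
  res <- smallRun()
  f <- frequencyValues(res)
  pl <- b$truth$plantedReceptors
  expect_gte(min(f[pl]), 0.9)
  # the planted module fills the top of the ranking
  top <- names(sort(f, decreasing = TRUE))[seq_along(pl)]
  expect_gte(mean(top %in% pl), 0.8)

  # a null bundle still runs end to end and yields valid frequencies
  nb <- generateNullData(smallConfig(), seed = 7)
  nres <- suppressWarnings(
    runComberon(nb$datasetA, nb$truth$receptors, nb$network,
                partner = nb$datasetB, homologs = nb$homologs,
                config = comberonConfig(nResamples = 20), seed = 11))
  fn <- frequencyValues(nres)
  expect_true(all(fn >= 0 & fn <= 1))
  expect_identical(length(nb$truth$plantedReceptors), 0L)
})

test_that("fixture bundles round-trip through the loaders", {
  dir <- withr::local_tempdir()
  writeFixtures(dir, config = smallConfig(), seed = 5)
  files <- c("expressionA.tsv", "annotationsA.tsv", "expressionB.tsv",
             "annotationsB.tsv", "network.tsv", "homologs.tsv",
             "known_pairs.tsv", "truth.json")
  expect_true(all(file.exists(file.path(dir, files))))
  ds <- suppressWarnings(loadExpression(file.path(dir, "expressionA.tsv"),
                                        file.path(dir, "annotationsA.tsv"),
                                        targetClass = "target"))
  b <- generateComberonData(smallConfig(), seed = 5)
  expect_identical(exprValues(ds), exprValues(b$datasetA))
  net <- loadNetwork(file.path(dir, "network.tsv"))
  expect_identical(networkEdges(net), b$network@edges)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_identical(sort(truth$plantedReceptors),
                   sort(b$truth$plantedReceptors))
  expect_true(all(truth$plantedReceptors %in% truth$receptors))
})

test_that("scrambled conservation removes the cross-species signal", {
  cfg <- smallConfig(conservationScramble = 1)
  b <- generateComberonData(cfg, seed = 9)
  # species B planted module lost its latent factor entirely
  plB <- paste0(b$truth$plantedReceptors, "B")
  xB <- exprValues(b$datasetB)[plB, targetCells(b$datasetB)]
  cmB <- cor(t(xB))
  expect_lt(mean(cmB[upper.tri(cmB)]), 0.1)
})
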