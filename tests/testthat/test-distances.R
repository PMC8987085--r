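test_that("correlation distance matches hand computation", {
  # 3 target cells; g = (1,2,3), r = (3,2,1): Pearson r = -1, distance 2
  v <- rbind(G1 = c(1, 2, 3), RCP = c(3, 2, 1), G2 = c(1, 2, 3))
  colnames(v) <- paste0("c", 1:3)
  ds <- makeDataset(v, sample = rep("s1", 3), cellClass = rep("target", 3))
  sd1 <- sampleDistance(ds, "RCP", "s1", metric = "correlation",
                        fractionCutoff = 0, minCells = 3)
  expect_equal(unname(sd1@D["RCP", "RCP"]), 0)
  expect_equal(unname(sd1@D["G1", "RCP"]), 2)
  expect_equal(unname(sd1@D["G2", "RCP"]), 2)
})

test_that("genes below the expression-fraction cutoff are excluded", {
  set.seed(3)
  n <- 100
  v <- rbind(RARE = c(rep(1, 4), rep(0, n - 4)),   # 4% of cells
             COMMON = runif(n) + 0.5,
             RCP = runif(n) + 0.5)
  colnames(v) <- paste0("c", seq_len(n))
  ds <- makeDataset(v, sample = rep("s1", n), cellClass = rep("target", n))
  sd1 <- sampleDistance(ds, "RCP", "s1", fractionCutoff = 0.05)
  expect_false("RARE" %in% rownames(sd1@D))
  expect_true("COMMON" %in% rownames(sd1@D))
})

test_that("small samples are skipped with a warning", {
  v <- matrix(1, 3, 4, dimnames = list(paste0("G", 1:3), paste0("c", 1:4)))
  ds <- makeDataset(v, sample = rep("s1", 4), cellClass = rep("target", 4))
  expect_warning(out <- sampleDistance(ds, "G1", "s1", minCells = 10),
                 "skipped")
  expect_null(out)
})

test_that("median aggregation follows the stated missing-value rules", {
  mk <- function(id, genes, recs, vals) {
    new("SampleDistance", sampleId = id,
        D = matrix(vals, length(genes), length(recs),
                   dimnames = list(genes, recs)),
        metric = "correlation")
  }
  s1 <- mk("s1", c("G1", "G2"), "R", c(0.2, 0.7))
  s2 <- mk("s2", c("G1", "G2"), "R", c(0.4, 0.9))
  s3 <- mk("s3", "G1", "R", 0.9)  # G2 missing here
  agg <- aggregateMedian(list(s1, s2, s3), metric = "correlation")
  expect_equal(unname(agg@M["G1", "R"]), 0.4)
  expect_equal(unname(agg@M["G2", "R"]), 0.8)  # median of 2 values

  # gene never co-observed: imputed as 1 under correlation
  s4 <- mk("s4", "G3", "R2", 0.1)
  agg2 <- aggregateMedian(list(s1, s4), metric = "correlation")
  expect_equal(unname(agg2@M["G3", "R"]), 1)
  expect_equal(unname(agg2@M["G1", "R2"]), 1)

  # euclidean: imputed with the maximum of M
  e1 <- mk("s1", c("G1", "G2"), "R", c(2, 7.5))
  e1@metric <- "euclidean"
  e2 <- mk("s2", "G3", "R2", 3)
  e2@metric <- "euclidean"
  agg3 <- aggregateMedian(list(e1, e2), metric = "euclidean")
  expect_equal(unname(agg3@M["G3", "R"]), 7.5)
})

test_that("median aggregation equals a dense brute-force oracle", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(5:20, 1); m <- sample(3:8, 1); k <- sample(2:7, 1)
    genes <- paste0("G", seq_len(n)); recs <- paste0("R", seq_len(m))
    cube <- array(runif(n * m * k), c(n, m, k))
    cube[sample(length(cube), round(length(cube) * 0.3))] <- NA
    per <- lapply(seq_len(k), function(s) {
      D <- cube[, , s]
      dimnames(D) <- list(genes, recs)
      keepRows <- rowSums(!is.na(D)) > 0
      new("SampleDistance", sampleId = paste0("s", s),
          D = D[keepRows, , drop = FALSE], metric = "correlation")
    })
    agg <- aggregateMedian(per, metric = "correlation")
    oracle <- apply(cube, c(1, 2), function(x)
      if (all(is.na(x))) 1 else median(x, na.rm = TRUE))
    dimnames(oracle) <- list(genes, recs)
    expect_equal(agg@M[genes, recs], oracle, tolerance = 1e-12)
  }
})

test_that("resample plans are seeded, sized, and reproducible", {
  ids <- paste0("s", 1:5)
  p1 <- makeResamples(ids, N = 100, seed = 9)
  p2 <- makeResamples(ids, N = 100, seed = 9)
  expect_identical(p1@draws, p2@draws)
  expect_identical(length(p1@draws), 100L)
  expect_true(all(vapply(p1@draws, length, integer(1)) == 5L))
  expect_true(all(unlist(p1@draws) %in% ids))

  # degenerate single-sample pool: all draws identical
  expect_warning(p3 <- makeResamples("s1", N = 10, seed = 1), "fewer than 5")
  expect_true(all(vapply(p3@draws, identical, logical(1), y = "s1")))
})

test_that("pseudo-splitting partitions cells and preserves class ratios", {
  set.seed(5)
  nc <- 1000
  v <- matrix(runif(3 * nc), 3, nc,
              dimnames = list(paste0("G", 1:3), paste0("c", seq_len(nc))))
  cls <- rep(c("target", "other"), c(600, 400))
  ds <- makeDataset(v, sample = rep(c("s1", "s2"), each = nc / 2),
                    cellClass = cls)
  out <- pseudoSplit(ds, nParts = 10, seed = 2)
  sam <- cellSamples(out)
  expect_identical(length(unique(sam)), 10L)
  expect_identical(sort(names(sam)), sort(colnames(v)))  # partition covers all
  sizes <- table(sam)
  expect_true(max(sizes) - min(sizes) <= 1)
  # stratification: class ratio within +-2% per part
  for (p in unique(sam)) {
    cells <- names(sam)[sam == p]
    ratio <- mean(cellClasses(out)[cells] == "target")
    expect_true(abs(ratio - 0.6) <= 0.02)
  }

  tiny <- makeDataset(v[, 1:50], sample = rep("s1", 50),
                      cellClass = rep(c("target", "other"), 25))
  expect_error(pseudoSplit(tiny, nParts = 10, seed = 1), "cannot split")
})
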