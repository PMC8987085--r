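mkTrack <- function(name, values, order) {
  new("MeasureTrack", name = name,
      values = stats::setNames(values, order), missing = character())
}

test_that("combining constant tracks yields a constant 3/m profile", {
  m <- 60
  ord <- paste0("R", seq_len(m))
  tracks <- list(mkTrack("fraction", rep(2, m), ord),
                 mkTrack("enrichment", rep(5, m), ord),
                 mkTrack("conservation", rep(1, m), ord))
  pr <- combineMeasures(tracks, ord)
  expect_equal(pr@combo, rep(3 / m, m), tolerance = 1e-12)
})

test_that("combination equals a brute-force double smoothing oracle", {
  smoothOracle <- function(x, w) {
    n <- length(x); out <- numeric(n)
    left <- w %/% 2; right <- w - 1 - left
    for (i in seq_len(n)) {
      idx <- max(1, i - left):min(n, i + right)
      out[i] <- mean(x[idx])
    }
    out
  }
  m <- 101
  ord <- paste0("R", seq_len(m))
  delta <- numeric(m); delta[40] <- 7
  tracks <- list(mkTrack("fraction", delta, ord),
                 mkTrack("enrichment", numeric(m), ord),
                 mkTrack("conservation", numeric(m), ord))
  pr <- combineMeasures(tracks, ord, window = 21)
  want <- smoothOracle(smoothOracle(delta / sum(delta), 21), 21)
  expect_equal(pr@combo, want, tolerance = 1e-12)
  expect_identical(which.max(pr@combo), 40L)

  set.seed(31)
  x <- runif(m)
  tr2 <- list(mkTrack("fraction", x, ord),
              mkTrack("enrichment", runif(m), ord),
              mkTrack("conservation", runif(m), ord))
  pr2 <- combineMeasures(tr2, ord, window = 21)
  want2 <- smoothOracle(
    smoothOracle(tr2[[1]]@values / sum(tr2[[1]]@values), 21) +
    smoothOracle(tr2[[2]]@values / sum(tr2[[2]]@values), 21) +
    smoothOracle(tr2[[3]]@values / sum(tr2[[3]]@values), 21), 21)
  expect_equal(pr2@combo, unname(want2), tolerance = 1e-12)
})

test_that("smoothing preserves constants and interior mass", {
  expect_equal(movingAverage(rep(4.2, 50), 21), rep(4.2, 50))
  # signals supported away from the edges keep their mass exactly
  x <- numeric(200)
  x[60:140] <- runif(81)
  expect_equal(sum(movingAverage(x, 21)), sum(x), tolerance = 1e-9)
  expect_equal(sum(movingAverage(movingAverage(x, 21), 21)), sum(x),
               tolerance = 1e-9)
})

test_that("combination is equivariant under reordering", {
  m <- 80
  ord <- paste0("R", seq_len(m))
  set.seed(32)
  tracks <- list(mkTrack("fraction", runif(m), ord),
                 mkTrack("enrichment", runif(m), ord),
                 mkTrack("conservation", runif(m), ord))
  ord2 <- sample(ord)
  p1 <- combineMeasures(tracks, ord)
  p2 <- combineMeasures(tracks, ord2)
  expect_identical(length(p2@combo), length(p1@combo))
  # a single interior spike: the peak follows the spiked receptor wherever
  # the order places it (interior, so edge renormalization plays no role)
  delta <- numeric(m); delta[40] <- 1
  tr <- list(mkTrack("fraction", delta, ord),
             mkTrack("enrichment", numeric(m), ord),
             mkTrack("conservation", numeric(m), ord))
  pA <- combineMeasures(tr, ord)
  ord3 <- c(setdiff(ord, "R40")[1:49], "R40", setdiff(ord, "R40")[50:79])
  pB <- combineMeasures(tr, ord3)
  expect_identical(pB@order[which.max(pB@combo)], "R40")
  expect_identical(pA@order[which.max(pA@combo)], "R40")
})

test_that("main peak members form the half-height run around the apex", {
  m <- 25
  ord <- paste0("R", seq_len(m))
  s <- pmax(0, 10 - 2 * abs(seq_len(m) - 10))  # triangle peaking at 10
  pr <- new("CombinationProfile", order = ord, combo = s,
            components = list(), window = 21L)
  pk <- mainPeak(pr)
  expect_identical(pk@apex, 10L)
  want <- ord[which(s >= 5)]
  expect_identical(pk@members, want)
  expect_true(all(diff(match(pk@members, ord)) == 1))

  # plateau maximum: leftmost index wins
  s2 <- c(0, 1, 3, 3, 3, 1, 0)
  pr2 <- new("CombinationProfile", order = paste0("R", 1:7), combo = s2,
             components = list(), window = 21L)
  expect_identical(mainPeak(pr2)@apex, 3L)

  # a distant second lobe above half height is not contiguous: excluded
  s3 <- c(1, 8, 10, 8, 1, 0.4, 1, 6, 7, 6, 1)
  pr3 <- new("CombinationProfile", order = paste0("R", 1:11), combo = s3,
             components = list(), window = 21L)
  expect_identical(mainPeak(pr3)@members, paste0("R", 2:4))

  przero <- new("CombinationProfile", order = "R1", combo = 0,
                components = list(), window = 21L)
  expect_error(mainPeak(przero), "zero")
})

test_that("peak sets apply height, prominence and separation rules", {
  mkProfile <- function(s) new("CombinationProfile",
                               order = paste0("R", seq_along(s)), combo = s,
                               components = list(), window = 21L)
  tri <- function(center, height, width, m) {
    pmax(0, height * (1 - abs(seq_len(m) - center) / width))
  }
  # single triangular peak
  ps1 <- allPeaks(mkProfile(tri(50, 1, 10, 100)), minSeparation = 50)
  expect_identical(ps1@main@apex, 50L)
  expect_identical(length(ps1@secondary), 0L)

  # two equal peaks 60 apart with a deep valley: both kept
  s2 <- tri(30, 1, 10, 120) + tri(90, 1, 10, 120)
  ps2 <- allPeaks(mkProfile(s2), minSeparation = 50)
  expect_identical(sort(c(ps2@main@apex,
                          vapply(ps2@secondary, function(p) p@apex,
                                 integer(1)))), c(30L, 90L))

  # two peaks 30 apart: only the higher survives the separation rule
  s3 <- tri(40, 1, 8, 120) + tri(70, 0.6, 8, 120)
  ps3 <- allPeaks(mkProfile(s3), minSeparation = 50)
  expect_identical(ps3@main@apex, 40L)
  expect_identical(length(ps3@secondary), 0L)

  # membership cap keeps the positions nearest the apex
  s4 <- rep(1, 200); s4[100] <- 1.2
  ps4 <- allPeaks(mkProfile(s4), maxMembers = 50)
  expect_lte(length(ps4@main@members), 50L)
  expect_true("R100" %in% ps4@main@members)
})

test_that("peak grouping recovers block structure with verifiable density", {
  mkPeak <- function(members, apex, h) new("Peak", apex = as.integer(apex),
                                           height = h, prominence = h,
                                           members = members)
  groupA <- paste0("R", 1:5); groupB <- paste0("Q", 1:4)
  sets <- lapply(1:10, function(i) {
    if (i <= 6) new("PeakSet", main = mkPeak(groupA, 3, 1),
                    secondary = list(mkPeak(groupB, 60, 0.5)))
    else new("PeakSet", main = mkPeak(groupB, 60, 1), secondary = list())
  })
  tab <- groupPeaks(sets, nGroups = 2, minDensity = 0.5)
  expect_gte(nrow(tab), 2)
  expect_true(all(tab$density >= 0.5))
  members <- lapply(tab$receptors, sort)
  expect_true(any(vapply(members, identical, logical(1), y = sort(groupA))))
  expect_true(any(vapply(members, identical, logical(1), y = sort(groupB))))
  # density is recomputable by brute force: all-identical case
  sets2 <- lapply(1:4, function(i) new("PeakSet", main = mkPeak(groupA, 3, 1),
                                       secondary = list()))
  tab2 <- groupPeaks(sets2, nGroups = 15, minDensity = 0.5)
  expect_identical(nrow(tab2), 1L)
  expect_equal(tab2$density, 1)
  expect_equal(tab2$meanFrequency, 1)
})

test_that("bootstrap frequencies are reproducible multiples of 1/N", {
  b <- smallBundle()
  cfg <- comberonConfig(nResamples = 20)
  r1 <- runComberon(b$datasetA, b$truth$receptors, b$network,
                    partner = b$datasetB, homologs = b$homologs,
                    config = cfg, seed = 5)
  r2 <- runComberon(b$datasetA, b$truth$receptors, b$network,
                    partner = b$datasetB, homologs = b$homologs,
                    config = cfg, seed = 5)
  expect_identical(frequencyValues(r1), frequencyValues(r2))
  f <- frequencyValues(r1)
  expect_true(all(abs(f * 20 - round(f * 20)) < 1e-9))
  expect_true(all(f >= 0 & f <= 1))
})
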