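test_that("pair combination is the scaled outer mean", {
  lv <- stats::setNames(c(0, 2, 5), paste0("L", 1:3))
  rv <- stats::setNames(c(1, 3), paste0("R", 1:2))
  cm <- pairCombo(lv, rv)
  expect_equal(unname(cm["L3", "R2"]), 1)            # both maxima
  expect_equal(unname(cm["L2", "R1"]), (0.4 + 0) / 2)
  # rank-1 structure: equals outer sum of the scaled vectors over two
  sl <- (lv - min(lv)) / diff(range(lv))
  sr <- (rv - min(rv)) / diff(range(rv))
  expect_equal(cm, outer(sl, sr, "+") / 2, tolerance = 1e-12)

  set.seed(51)
  a <- stats::setNames(runif(10), paste0("L", 1:10))
  b <- stats::setNames(runif(7), paste0("R", 1:7))
  expect_equal(pairCombo(a, b),
               outer(minMaxScale(a), minMaxScale(b), "+") / 2,
               tolerance = 1e-12)
})

test_that("neighborhood frequencies count window co-membership", {
  ord <- paste0("G", 1:10)
  nf <- neighborhoodFrequencies(list(ord), genes = ord, window = 4)
  # window of 4 at position 5: positions 3..6
  expect_equal(unname(nf["G5", c("G3", "G6")]), c(1, 1))
  expect_equal(unname(nf["G5", "G8"]), 0)
  # window monotonicity: wider windows never lose neighbors
  nf2 <- neighborhoodFrequencies(list(ord), genes = ord, window = 8)
  expect_true(all(nf2 >= nf))
  # two discordant orders average to 0.5 where they disagree
  nfm <- neighborhoodFrequencies(list(ord, rev(ord)), genes = ord,
                                 window = 4)
  expect_true(all(nfm %in% c(0, 0.5, 1)))
})

test_that("known-pair counts respect the presence threshold strictly", {
  lg <- paste0("L", 1:4); rg <- paste0("R", 1:4)
  NL <- matrix(0, 4, 4, dimnames = list(lg, lg)); diag(NL) <- 1
  NL["L1", "L2"] <- 0.3   # exactly at the threshold: excluded
  NL["L1", "L3"] <- 0.31
  NR <- matrix(0, 4, 4, dimnames = list(rg, rg)); diag(NR) <- 1
  kp <- KnownPairList(c("L3", "L2"), c("R2", "R4"))
  cnt <- neighborKnownPairs(NL, NR, kp, presence = 0.3)
  expect_identical(unname(cnt["L1", "R2"]), 1L)  # via L3 at 0.31
  expect_identical(unname(cnt["L1", "R4"]), 0L)  # L2 at exactly 0.30
  empty <- neighborKnownPairs(NL, NR, KnownPairList(character(), character()))
  expect_true(all(empty == 0))
})

test_that("display matrix masks at 0.5 strictly and reports correlations", {
  cm <- matrix(c(0.2, 0.9, 0.5, 1), 2, 2,
               dimnames = list(c("L1", "L2"), c("R1", "R2")))
  nk <- matrix(c(0, 3, 1, 4), 2, 2, dimnames = dimnames(cm))
  pm <- pairDisplay(cm, nk)
  nks <- (nk - min(nk)) / diff(range(nk))
  expect_equal(pm@display, (cm + nks) / 2, tolerance = 1e-12)
  expect_identical(unname(pm@shown["L2", "R2"]), TRUE)
  expect_false(pm@shown["L1", "R1"])
  expect_true(is.numeric(pm@correlations$pearson$estimate))

  # all-zero neighborhood counts: display halves the combo, nothing shown
  # when the combo never exceeds 1
  nk0 <- matrix(0, 2, 2, dimnames = dimnames(cm))
  pm0 <- pairDisplay(cm, nk0)
  expect_equal(pm0@display, cm / 2, tolerance = 1e-12)
  expect_true(all(!pm0@shown))
  expect_null(pm0@correlations$pearson)

  # display exactly 0.5 is masked (strictly above)
  cmE <- matrix(c(1, 0), 1, 2, dimnames = list("L1", c("R1", "R2")))
  nkE <- matrix(c(0, 1), 1, 2, dimnames = dimnames(cmE))
  pmE <- pairDisplay(cmE, nkE)
  expect_equal(unname(pmE@display[1, ]), c(0.5, 0.5))
  expect_true(all(!pmE@shown))
})

test_that("hotspot boxes bound the densest shown block", {
  mkPM <- function(display) {
    shown <- display > 0.5
    new("PairMatrix", ligands = rownames(display),
        receptors = colnames(display), comboMean = display,
        neighborKnown = display, display = display, shown = shown,
        correlations = list())
  }
  d <- matrix(0, 20, 20, dimnames = list(paste0("L", 1:20),
                                         paste0("R", 1:20)))
  d[3:7, 4:8] <- 0.8
  box <- hotspotBox(mkPM(d))
  expect_identical(box$rowRange, c(3L, 7L))
  expect_identical(box$colRange, c(4L, 8L))

  # two blocks: the higher-valued one is chosen
  d2 <- d; d2[13:17, 12:16] <- 0.95
  box2 <- hotspotBox(mkPM(d2))
  expect_identical(box2$rowRange, c(13L, 17L))

  expect_null(hotspotBox(mkPM(matrix(0, 5, 5,
    dimnames = list(paste0("L", 1:5), paste0("R", 1:5))))))
})

test_that("pair matrices export to long-format TSV", {
  cm <- matrix(runif(6), 2, 3, dimnames = list(paste0("L", 1:2),
                                               paste0("R", 1:3)))
  pm <- pairDisplay(cm, matrix(rpois(6, 2), 2, 3, dimnames = dimnames(cm)))
  dir <- withr::local_tempdir()
  writePairMatrix(pm, file.path(dir, "pm.tsv"))
  tab <- read.delim(file.path(dir, "pm.tsv"))
  expect_identical(nrow(tab), 6L)
  expect_identical(sort(unique(tab$ligand)), c("L1", "L2"))
  i <- which(tab$ligand == "L2" & tab$receptor == "R3")
  expect_equal(tab$display[i], unname(pm@display["L2", "R3"]))
})
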