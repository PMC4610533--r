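test_that("adhesion flags follow the area/roundness rule and its knobs", {
  p <- workParams()
  props <- data.frame(label = 1:4,
                      area = c(4000, 3000, 4000, 3400),
                      roundness = c(3.5, 1.2, 1.5, 3.5))
  # default rule: either signal suffices
  expect_equal(detectAdhesion(props, p), c(TRUE, FALSE, TRUE, TRUE))
  pb <- workParams(adhesionRule = "both")
  expect_equal(detectAdhesion(props, pb), c(TRUE, FALSE, FALSE, FALSE))
  pl <- workParams(adhesionRule = "both", adhesionComparator = "less")
  expect_equal(detectAdhesion(props, pl), c(FALSE, FALSE, TRUE, FALSE))
})

test_that("marked watershed splits along the bisector of two disks", {
  o <- matrix(0L, 60, 90)
  o[diskMask(60, 90, 30, 30, 20) > 0] <- 1L
  o[diskMask(60, 90, 30, 60, 20) > 0] <- 1L
  mk <- matrix(0L, 60, 90); mk[30, 30] <- 1L; mk[30, 60] <- 2L
  w <- markedWatershed(o, mk)
  expect_equal(sort(unique(as.vector(w[o > 0]))), c(1L, 2L))
  expect_true(all(w[o == 0] == 0))
  # boundary within 2 px of the perpendicular bisector (column 45)
  wrong <- sum(w == 1 & col(w) > 47) + sum(w == 2 & col(w) < 43)
  expect_equal(wrong, 0)
  # a single marker floods its whole component
  one <- markedWatershed(o, (mk == 1) * 1L)
  expect_equal((one > 0) * 1L, o)
  expect_error(markedWatershed(o, matrix(0L, 60, 90)), "marker")
})

test_that("marked watershed equals the priority-flood oracle on random masks", {
  set.seed(19)
  for (i in 1:40) {
    n <- sample(12:24, 1)
    m <- matrix(rbinom(n * n, 1, 0.6), n)
    lab <- connectedComponents(m, 4)
    if (max(lab) == 0) next
    mk <- matrix(0L, n, n)
    fg <- which(m > 0)
    seedpix <- sample(fg, min(length(fg), sample(1:4, 1)))
    mk[seedpix] <- seq_along(seedpix)
    surf <- -distanceTransform(m)
    expect_equal(markedWatershed(m, mk),
                 watershedOracle(surf, mk, m > 0))
  }
})

test_that("adaptive splitting separates dumbbells and leaves disks alone", {
  p <- workParams()
  # dumbbell of radius-12 disks, centers 20 apart: the waist saddle sits
  # below the extremum level, so two extremum regions appear
  m <- matrix(0L, 50, 70)
  m[diskMask(50, 70, 25, 25, 12) > 0] <- 1L
  m[diskMask(50, 70, 25, 45, 12) > 0] <- 1L
  sp <- adaptiveSplit(m, p)
  expect_equal(length(setdiff(unique(as.vector(sp)), 0L)), 2)
  expect_true(attr(sp, "how") %in% c("extremum", "erosion"))
  # convex disk: no spurious split
  d <- diskMask(70, 70, 35, 35, 30)
  spd <- adaptiveSplit(d, p)
  expect_equal(max(spd), 1)
  # thin sliver that erodes away unsplit
  sl <- matrix(0L, 30, 30); sl[15:16, 5:25] <- 1L
  sps <- adaptiveSplit(sl, p)
  expect_equal(attr(sps, "how"), "unsplit")
  expect_equal((sps > 0) * 1L, sl)
  # a merged nucleus seed guides the split when the region shape cannot
  reg <- matrix(0L, 80, 110)
  reg[diskMask(80, 110, 40, 45, 26) > 0] <- 1L
  reg[diskMask(80, 110, 40, 67, 26) > 0] <- 1L
  seed <- matrix(0L, 80, 110)
  seed[diskMask(80, 110, 40, 44, 14) > 0] <- 1L
  seed[diskMask(80, 110, 40, 68, 14) > 0] <- 1L
  sps2 <- adaptiveSplit(reg, p, seedMask = seed)
  expect_equal(attr(sps2, "how"), "seed")
  expect_equal(length(setdiff(unique(as.vector(sps2)), 0L)), 2)
})

test_that("cell separation recovers overlapping cells with their nuclei", {
  p <- workParams()
  # five mutually overlapping cells, five seeds
  sc <- makeSmear(imageSize = c(360, 420), nWbc = 5, nRbc = 0,
                  overlapFraction = 1, seed = 700)
  outT <- (wbcLabels(sc) > 0) * 1L
  inT <- (nucleusLabels(sc) > 0) * 1L
  labs <- separateWbcs(outT, inT, p)
  expect_equal(max(labs), 5)
  nuc <- nucleusLabels(sc)
  for (lb in 1:5) {
    inside <- unique(nuc[labs == lb & nuc > 0])
    expect_equal(length(inside), 1)  # exactly one nucleus per cell
  }
  # merged nuclei force the second pass
  scm <- makeSmear(imageSize = c(360, 420), nWbc = 2, nRbc = 0,
                   overlapFraction = 1, seed = 701, mergedNuclei = TRUE)
  labm <- separateWbcs((wbcLabels(scm) > 0) * 1L,
                       (nucleusLabels(scm) > 0) * 1L, p)
  expect_equal(max(labm), 2)
  expect_true("split_pass2" %in% attr(labm, "provenance"))
  # isolated cells exit early untouched
  sci <- makeSmear(imageSize = c(300, 400), nWbc = 3, nRbc = 0, seed = 702)
  outI <- (wbcLabels(sci) > 0) * 1L
  labi <- separateWbcs(outI, (nucleusLabels(sci) > 0) * 1L, p)
  expect_equal(labi, connectedComponents(outI),
               ignore_attr = TRUE)
  expect_true(all(attr(labi, "provenance") == "single"))
})

test_that("labels never grow beyond the cell-mask support", {
  p <- workParams()
  for (s in 1:5) {
    sc <- makeSmear(imageSize = c(320, 400), nWbc = 4, nRbc = 0,
                    overlapFraction = 0.5, seed = 710 + s)
    outT <- (wbcLabels(sc) > 0) * 1L
    labs <- separateWbcs(outT, (nucleusLabels(sc) > 0) * 1L, p)
    expect_true(all(labs[outT == 0] == 0))
    # every mask pixel is assigned: the partition accounts for the mask
    expect_true(all(labs[outT == 1] > 0))
    k <- max(labs)
    expect_gte(k, max(connectedComponents(outT)))
  }
})

test_that("post-processing assigns nuclei and removes impurities", {
  p <- workParams()
  wbcs <- matrix(0L, 40, 80)
  wbcs[diskMask(40, 80, 20, 15, 10) > 0] <- 1L  # real cell
  wbcs[diskMask(40, 80, 20, 45, 8) > 0] <- 2L   # impurity, no nucleus
  nuc <- matrix(0L, 40, 80)
  nuc[diskMask(40, 80, 20, 15, 5) > 0] <- 1L
  res <- postprocessSegmentation(wbcs, nuc, p)
  expect_equal(max(wbcLabels(res)), 1)
  expect_equal(sum(wbcLabels(res) == 1), sum(wbcs == 1))
  expect_true(all(nucleusLabels(res)[nuc == 1] == 1))
  # a nucleus straddling a label boundary is split by the AND
  wbcs2 <- matrix(0L, 40, 80)
  wbcs2[, 1:40][diskMask(40, 40, 20, 20, 15) > 0] <- 1L
  wbcs2[, 41:80][diskMask(40, 40, 20, 20, 15) > 0] <- 2L
  nuc2 <- matrix(0L, 40, 80)
  nuc2[18:22, 35:46] <- 1L
  res2 <- postprocessSegmentation(wbcs2, nuc2, p)
  nl <- nucleusLabels(res2)
  expect_equal(sort(unique(nl[nl > 0])), c(1L, 2L))
  # empty nucleus mask removes everything
  res0 <- postprocessSegmentation(wbcs, matrix(0L, 40, 80), p)
  expect_equal(max(wbcLabels(res0)), 0)
  expect_equal(nrow(regionTable(res0)), 0)
})
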