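test_that("mean-shift filtering preserves flat structure", {
  const <- matrix(42, 12, 12)
  expect_equal(meanShiftFilter(const, 3, 3), const)
  # two flat regions far beyond the range bandwidth stay untouched
  two <- matrix(40, 16, 16); two[, 9:16] <- 200
  expect_equal(meanShiftFilter(two, 3, 3), two)
  # a lone pixel within hr of its flat surround is pulled into it
  p <- matrix(98, 9, 9); p[5, 5] <- 100
  f <- meanShiftFilter(p, 3, 3, 4, 0.5)
  expect_gte(f[5, 5], 97); expect_lte(f[5, 5], 99)
})

test_that("mean-shift filtering is a contraction of the intensity range", {
  set.seed(12)
  for (i in 1:10) {
    pl <- matrix(sample(0:255, 20 * 20, TRUE), 20)
    f <- meanShiftFilter(pl, sample(1:4, 1), runif(1, 1, 20))
    expect_gte(min(f), min(pl))
    expect_lte(max(f), max(pl))
  }
})

test_that("mean-shift filtering equals the window-mean iteration oracle", {
  set.seed(8)
  for (i in 1:20) {
    pl <- matrix(sample(0:255, 16 * 16, TRUE), 16)
    hs <- sample(1:3, 1); hr <- sample(c(3, 8, 15), 1)
    expect_equal(meanShiftFilter(pl, hs, hr), meanShiftOracle(pl, hs, hr))
  }
})

test_that("adaptive threshold meets the background pixel budget", {
  # 70% at 10, 30% at 200; nucleus a tenth of the image at N = 3
  pl <- matrix(c(rep(10, 70), rep(200, 30)), 10)
  t3 <- adaptiveThresholdFraction(pl, nucleusArea = 10, N = 3)
  expect_equal(t3, 10)
  expect_equal(sum(pl > t3), 30)
  # no nucleus: threshold rises to the top occupied level, empty foreground
  t0 <- adaptiveThresholdFraction(pl, 0, 3)
  expect_equal(t0, 200)
  expect_equal(sum(pl > t0), 0)
  # impossible budget degrades with a warning
  expect_warning(tw <- adaptiveThresholdFraction(pl, 60, 3), "exceeds")
  expect_equal(tw, 0)
})

test_that("adaptive threshold is monotone and obeys the tie-mass bound", {
  set.seed(21)
  for (i in 1:60) {
    pl <- matrix(sample(0:255, 256, TRUE, prob = runif(256)^2), 16)
    n <- length(pl)
    areas <- sort(sample(0:floor(n / 3), 4))
    th <- vapply(areas, function(a) adaptiveThresholdFraction(pl, a, 3),
                 numeric(1))
    expect_true(all(diff(th) <= 0))    # larger nucleus, lower threshold
    ratios <- c(1.5, 2, 3)
    th2 <- vapply(ratios, function(nn)
      adaptiveThresholdFraction(pl, areas[2], nn), numeric(1))
    expect_true(all(diff(th2) <= 0))   # larger N, lower threshold
    # foreground never exceeds the budget by more than one bin's mass
    a <- areas[3]
    tg <- adaptiveThresholdFraction(pl, a, 3)
    maxBin <- max(tabulate(as.integer(pl) + 1L, 256))
    expect_lte(sum(pl > tg) / n, 3 * a / n + maxBin / n)
  }
})

test_that("cluster and enhancement masks both recover the cells", {
  p <- workParams()
  sc <- makeSmear(imageSize = c(260, 340), nWbc = 3, nRbc = 40, seed = 600)
  img <- smearImage(sc)
  truthN <- sum(nucleusLabels(sc) > 0)
  truth <- wbcLabels(sc)
  for (fn in c(wbcClusterMask, wbcEnhancedMask)) {
    m <- fn(img, truthN, p)
    m <- denoiseSmall(m, p@minCellArea)
    for (lb in seq_len(max(truth))) {
      cell <- truth == lb
      expect_gte(sum(m[cell]) / sum(cell), 0.6)
    }
  }
  # no cells in a cell-free image
  sc0 <- makeSmear(imageSize = c(200, 260), nWbc = 0, nRbc = 30, seed = 601)
  expect_equal(sum(buildOutsideSeeds(smearImage(sc0), 0, p)), 0)
})

test_that("bandwidth settings change the cluster mask", {
  p <- workParams()
  sc <- makeSmear(imageSize = c(220, 280), nWbc = 2, nRbc = 30, seed = 610)
  img <- smearImage(sc)
  na <- sum(nucleusLabels(sc) > 0)
  m33 <- wbcClusterMask(img, na, p)
  m113 <- wbcClusterMask(img, na, workParams(spatialBandwidth = 1, rangeBandwidth = 13))
  m131 <- wbcClusterMask(img, na, workParams(spatialBandwidth = 13, rangeBandwidth = 1))
  expect_gt(sum(m33 != m113) + sum(m33 != m131), 0)
  expect_gt(sum(m33), 0)
})

test_that("outside seeds union the strategies, denoise and contain the seeds", {
  p <- workParams()
  sc <- makeSmear(imageSize = c(300, 400), nWbc = 6, nRbc = 50, seed = 620)
  img <- smearImage(sc)
  seeds <- buildInsideSeeds(img, p)
  out <- buildOutsideSeeds(img, sum(insideSeeds(seeds)), p)
  truth <- wbcLabels(sc)
  for (lb in seq_len(max(truth))) {
    cell <- truth == lb
    expect_gte(sum(out[cell]) / sum(cell), 0.85)  # per-cell pixel recall
  }
  # every surviving component is at least the minimum cell area
  pr <- regionProps(connectedComponents(out))
  expect_true(all(pr$area >= p@minCellArea))
  # enhancement mask alone must already be in the union
  m2 <- wbcEnhancedMask(img, sum(insideSeeds(seeds)), p)
  m1 <- wbcClusterMask(img, sum(insideSeeds(seeds)), p)
  un <- ((m1 + m2) > 0)
  expect_true(all(un[m2 == 1]))
})

test_that("enhancement mask is robust to illumination scaling", {
  p <- workParams()
  a <- makeSmear(imageSize = c(220, 280), nWbc = 2, nRbc = 30,
                 illumination = 1, seed = 630)
  b <- makeSmear(imageSize = c(220, 280), nWbc = 2, nRbc = 30,
                 illumination = 0.7, seed = 630)
  na <- sum(nucleusLabels(a) > 0)
  ma <- wbcEnhancedMask(smearImage(a), na, p)
  mb <- wbcEnhancedMask(smearImage(b), na, p)
  expect_lte(mean(ma != mb), 0.02)
})
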