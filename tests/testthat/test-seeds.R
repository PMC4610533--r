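test_that("Otsu threshold maximizes between-class variance with smallest tie", {
  # perfectly separable two-spike histogram
  p <- matrix(c(rep(0, 50), rep(255, 50)), 10)
  t1 <- otsuThreshold(p)
  expect_equal(t1, otsuScanOracle(p))
  expect_true(all(p[p > t1] == 255) && all(p[p <= t1] == 0))
  # two-Gaussian mixture: the cut falls in the inter-mode gap (the
  # between-class variance is flat across the empty gap, and the
  # smallest-maximizer tie-break lands at its lower edge)
  set.seed(41)
  g <- matrix(pmin(255, pmax(0, c(rnorm(5000, 60, 10), rnorm(5000, 190, 10)))), 100)
  tg <- otsuThreshold(g)
  expect_gte(tg, 85); expect_lte(tg, 165)
  expect_equal(tg, otsuScanOracle(g))
  expect_lt(mean(g <= tg & g > 125), 0.001)  # upper mode stays foreground
  expect_lt(mean(g > tg & g < 125), 0.001)   # lower mode stays background
  # random planes against the exhaustive scan
  for (i in 1:10) {
    r <- matrix(sample(0:255, 400, TRUE), 20)
    expect_equal(otsuThreshold(r), otsuScanOracle(r))
  }
  expect_warning(tc <- otsuThreshold(matrix(7, 4, 4)), "constant")
  expect_equal(tc, 7)
})

test_that("nucleus segmentation finds the nucleus and only the nucleus", {
  p <- workParams()
  sc <- makeSmear(imageSize = c(200, 260), nWbc = 1, nRbc = 20, seed = 301)
  mask <- segmentNucleus(smearImage(sc), p)
  lab <- connectedComponents(mask)
  expect_equal(max(lab), 1)
  truth <- (nucleusLabels(sc) > 0) * 1L
  inter <- sum(mask & truth)
  iou <- inter / (sum(mask) + sum(truth) - inter)
  expect_gte(iou, 0.7)
  # red cells and background only -> empty
  sc0 <- makeSmear(imageSize = c(200, 260), nWbc = 0, nRbc = 30, seed = 302)
  expect_equal(sum(segmentNucleus(smearImage(sc0), p)), 0)
  # achromatic image -> empty (saturation identically zero)
  gray <- array(128L, c(64, 64, 3))
  expect_equal(sum(suppressWarnings(segmentNucleus(gray, p))), 0)
})

test_that("multi-core pairing respects the area window and gap threshold", {
  p <- workParams()
  base <- matrix(0L, 120, 200)
  mk <- function(m, cy, cx, r) { m[diskMask(120, 200, cy, cx, r) > 0] <- 1L; m }
  # two cores ~area 450/700, gap ~30: one pair
  m <- mk(mk(base, 60, 50, 12), 60, 110, 15)
  pares <- findMultiCores(m, p)
  expect_equal(nrow(pares), 1)
  expect_equal(pares$dist, 60 - 12 - 15, tolerance = 1.5)
  # one core too big (area > 950): no pair
  m2 <- mk(mk(base, 60, 50, 12), 60, 120, 25)
  expect_equal(nrow(findMultiCores(m2, p)), 0)
  # gap beyond the threshold: no pair
  m3 <- mk(mk(base, 60, 30, 12), 60, 130, 12)  # gap = 100 - 24 = 76
  expect_equal(nrow(findMultiCores(m3, p)), 0)
})

test_that("centroid connection fills the padded clamped rectangle", {
  p <- workParams()
  m <- matrix(0L, 100, 100)
  m[diskMask(100, 100, 10, 10, 7) > 0] <- 1L
  m[diskMask(100, 100, 20, 20, 7) > 0] <- 1L
  before <- max(connectedComponents(m))
  pares <- findMultiCores(m, p)
  skip_if(nrow(pares) == 0)
  out <- centroidConnect(m, pares[1, ], p)
  expect_equal(max(connectedComponents(out)), before - 1)
  # rectangle spans [min-5, max+5] on both axes, clamped at 1
  expect_true(all(out[5:25, 5:25] == 1))
  expect_true(all(out >= m))
  # single core: nothing to connect
  s <- matrix(0L, 50, 50); s[diskMask(50, 50, 25, 25, 8) > 0] <- 1L
  expect_equal(nrow(findMultiCores(s, p)), 0)
})

test_that("rectangle arithmetic matches the direct formula with clamping", {
  set.seed(55)
  for (i in 1:50) {
    dims <- c(sample(40:120, 1), sample(40:120, 1))
    xs <- runif(2, 1, dims[2]); ys <- runif(2, 1, dims[1])
    t2 <- sample(3:8, 1)
    r <- leukoSeg:::padRectangle(xs, ys, t2, dims)
    expect_equal(min(r$cols), max(round(min(xs)) - t2, 1))
    expect_equal(max(r$cols), min(round(max(xs)) + t2, dims[2]))
    expect_equal(min(r$rows), max(round(min(ys)) - t2, 1))
    expect_equal(max(r$rows), min(round(max(ys)) + t2, dims[1]))
  }
})

test_that("inside seeds collapse lobed nuclei without bridging cells", {
  p <- workParams()
  # three-lobed neutrophil: one seed component
  sc <- makeSmear(imageSize = c(200, 260), nWbc = 1, nRbc = 15,
                  lobesRange = c(3, 3), seed = 310)
  seeds <- buildInsideSeeds(smearImage(sc), p)
  expect_equal(max(connectedComponents(insideSeeds(seeds))), 1)
  # two well-separated cells stay two seeds
  sc2 <- makeSmear(imageSize = c(240, 320), nWbc = 2, nRbc = 15, seed = 311)
  seeds2 <- buildInsideSeeds(smearImage(sc2), p)
  expect_equal(max(connectedComponents(insideSeeds(seeds2))), 2)
  # empty nucleus mask -> empty seeds
  sc0 <- makeSmear(imageSize = c(200, 260), nWbc = 0, nRbc = 25, seed = 312)
  expect_equal(sum(insideSeeds(buildInsideSeeds(smearImage(sc0), p))), 0)
})

test_that("seed count equals cell count over many isolated scenes", {
  p <- workParams()
  hits <- 0
  for (s in 1:50) {
    n <- 1 + s %% 3
    sc <- makeSmear(imageSize = c(240, 320), nWbc = n, nRbc = 20,
                    lobesRange = c(1, 3), seed = 400 + s)
    k <- max(connectedComponents(insideSeeds(buildInsideSeeds(smearImage(sc), p))))
    hits <- hits + (k == n)
  }
  expect_gte(hits, 48)
})

test_that("nucleus segmentation is stable under illumination scaling", {
  p <- workParams()
  for (s in 1:5) {
    a <- makeSmear(imageSize = c(200, 260), nWbc = 2, nRbc = 25,
                   illumination = 1, seed = 500 + s)
    b <- makeSmear(imageSize = c(200, 260), nWbc = 2, nRbc = 25,
                   illumination = 0.55 + 0.09 * s, seed = 500 + s)
    ma <- segmentNucleus(smearImage(a), p)
    mb <- segmentNucleus(smearImage(b), p)
    expect_lte(mean(ma != mb), 0.02)
  }
})
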