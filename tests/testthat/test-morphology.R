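test_that("connected components agree with a flood-fill oracle", {
  empty <- matrix(0L, 6, 6)
  expect_equal(connectedComponents(empty), empty)
  diagm <- matrix(0L, 4, 4)
  diagm[2, 2] <- 1L; diagm[3, 3] <- 1L
  expect_equal(max(connectedComponents(diagm, 4)), 2)
  expect_equal(max(connectedComponents(diagm, 8)), 1)
  set.seed(31)
  for (i in 1:12) {
    m <- matrix(rbinom(64 * 64, 1, 0.4), 64)
    for (conn in c(4, 8))
      expect_equal(connectedComponents(m, conn), floodFillOracle(m, conn))
  }
})

test_that("small-component removal is strict, idempotent and monotone", {
  m <- matrix(0L, 30, 60)
  m[2:12, 2:10] <- 1L     # area 99
  m[2:11, 20:29] <- 1L    # area 100
  out <- denoiseSmall(m, 100)
  expect_equal(sum(out[, 1:12]), 0)     # 99 < 100 removed
  expect_equal(sum(out[, 20:29]), 100)  # exactly 100 kept
  expect_equal(denoiseSmall(out, 100), out)
  expect_equal(denoiseSmall(matrix(0L, 5, 5), 10), matrix(0L, 5, 5))
  expect_lte(sum(out), sum(m))
})

test_that("reconstruction keeps exactly the marked components", {
  m <- matrix(0L, 20, 40)
  m[2:6, 2:6] <- 1L; m[10:14, 10:14] <- 1L; m[2:6, 30:34] <- 1L
  marker <- matrix(0L, 20, 40)
  marker[3, 3] <- 1L; marker[12, 12] <- 1L
  out <- reconstructMask(marker, m)
  expect_equal(sum(out), 50)
  expect_true(all(out[m == 0] == 0))
  expect_equal(sum(out[, 30:34]), 0)
  # fixed point and degenerate marker
  expect_equal(reconstructMask(m, m), m)
  expect_equal(sum(reconstructMask(matrix(0L, 20, 40), m)), 0)
  # idempotence and anti-extensivity
  expect_equal(reconstructMask(out, m), out)
  # marker poking outside the mask is clipped, not an error
  marker2 <- marker; marker2[1, 38] <- 1L
  expect_equal(reconstructMask(marker2, m), out)
})

test_that("region features match analytic shapes and a boundary-walk oracle", {
  sq <- matrix(0L, 40, 40); sq[5:34, 5:34] <- 1L
  pr <- regionProps(connectedComponents(sq))
  expect_equal(pr$area, 900)
  expect_equal(pr$height, 30)
  expect_equal(pr$width, 30)
  expect_equal(pr$perimeter, 116)  # chain code: 4 * (side - 1)
  expect_equal(pr$roundness, 4 / pi, tolerance = 0.1)
  expect_equal(c(pr$cx, pr$cy), c(19.5, 19.5))

  disk <- diskMask(50, 50, 25, 25, 20)
  prd <- regionProps(connectedComponents(disk))
  expect_gt(prd$roundness, 0.95)
  expect_lt(prd$roundness, 1.15)

  single <- matrix(0L, 5, 5); single[3, 3] <- 1L
  prs <- regionProps(connectedComponents(single))
  expect_equal(prs$area, 1)
  expect_true(is.finite(prs$roundness))

  # random small 4-connected shapes against the independent walk
  set.seed(77)
  for (i in 1:25) {
    m <- matrix(rbinom(144, 1, 0.55), 12)
    lab <- connectedComponents(m, 4)
    if (max(lab) == 0) next
    big <- which.max(tabulate(lab[lab > 0]))
    shape <- (lab == big) * 1L
    pr1 <- regionProps(connectedComponents(shape))
    expect_equal(pr1$perimeter, chainWalkOracle(shape), tolerance = 1e-9)
    expect_equal(pr1$area, sum(shape))
    expect_gte(pr1$height * pr1$width, pr1$area)
  }
})

test_that("erosion and dilation behave like disk min/max filters", {
  disk <- diskMask(40, 40, 20, 20, 10)
  er <- binaryErode(disk, 3)
  expect_equal(sum(er), pi * 49, tolerance = 0.1 * pi * 49)
  expect_true(all(er[disk == 0] == 0))
  expect_equal(sum(binaryDilate(matrix(0L, 10, 10), 2)), 0)
  opened <- binaryDilate(binaryErode(disk, 3), 3)
  expect_true(all(opened <= disk))      # anti-extensivity of opening
  closed <- binaryClose(disk, 3)
  expect_true(all(closed >= disk))      # extensivity of closing
})

test_that("hole filling closes enclosed background only", {
  ring <- matrix(0L, 20, 20)
  ring[5:15, 5:15] <- 1L; ring[8:12, 8:12] <- 0L
  filled <- fillHoles(ring)
  expect_equal(sum(filled), 121)
  border <- matrix(0L, 10, 10); border[1, ] <- 1L
  expect_equal(fillHoles(border), border)
})
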