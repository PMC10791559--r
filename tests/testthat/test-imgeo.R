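# Image geometry: contours, rim distance, projections, reslicing.

test_that("contour rasterization matches pixel-center membership and shoelace area", {
  # rectangle covering the whole frame -> all-true mask
  full <- maskFromContour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
                          planeShape = c(10, 10), pixelXY = 0.1)
  expect_true(all(maskValues(full)))
  expect_equal(maskArea(full), 1)

  # rasterized area agrees with the shoelace polygon area to within a
  # one-pixel band around the perimeter
  set.seed(5)
  for (i in 1:10) {
    nv <- sample(3:7, 1)
    ang <- sort(runif(nv, 0, 2 * pi))
    r <- runif(nv, 0.5, 1.8)
    vx <- 2 + r * cos(ang); vy <- 2 + r * sin(ang)
    m <- maskFromContour(cbind(vx, vy), c(40, 40), 0.1)
    shoelace <- abs(sum(vx * c(vy[-1], vy[1]) - c(vx[-1], vx[1]) * vy)) / 2
    perim <- sum(sqrt(diff(c(vx, vx[1]))^2 + diff(c(vy, vy[1]))^2))
    expect_lt(abs(maskArea(m) - shoelace), perim * 0.1 + 0.01)
  }

  expect_error(maskFromContour(cbind(c(0, 1), c(0, 1)), c(10, 10), 0.1),
               "3 vertices")
  expect_error(maskFromContour(cbind(c(0, 1, 2), c(0, 1, 2)), c(40, 40), 0.1),
               "degenerate")
})

test_that("rim mask equals the brute-force distance computation", {
  # 10x10 square at 0.1 um/pixel: max interior distance 0.5 um, so a 1-um
  # rim is the whole square
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE
  cell <- regionMask(sq, 0.1)
  expect_identical(maskValues(rimMask(cell, 1.0)), sq)

  # width 0 -> empty rim
  expect_equal(sum(maskValues(rimMask(cell, 0))), 0)

  # random blobs vs O(n^2) oracle
  set.seed(11)
  for (i in 1:6) {
    m <- randomBlobMask()
    if (!any(m)) next
    w <- runif(1, 0.05, 0.4)
    got <- maskValues(rimMask(regionMask(m, 0.1), w))
    expect_identical(got, bruteRim(m, w, 0.1))
  }

  # monotone in width; converges to the full cell
  m <- randomBlobMask()
  r1 <- maskValues(rimMask(regionMask(m, 0.1), 0.1))
  r2 <- maskValues(rimMask(regionMask(m, 0.1), 0.3))
  expect_true(all(r2[r1]))
  expect_identical(maskValues(rimMask(regionMask(m, 0.1), 100)), m)

  expect_error(rimMask(regionMask(matrix(FALSE, 4, 4), 0.1), 1), "empty")
})

test_that("z-projection of maxima matches a per-pixel loop", {
  one <- imageStack(array(runif(30), c(5, 6, 1, 1)), 0.1, 0.3)
  expect_equal(zprojectMax(one, 1), voxels(one)[, , 1, 1])

  a <- array(0, c(4, 4, 3)); a[, , 2] <- 1
  expect_true(all(zprojectMax(imageStack(a, 0.1, 0.3), 1) == 1))

  set.seed(2)
  arr <- array(runif(5 * 7 * 4), c(5, 7, 4))
  stk <- imageStack(arr, 0.1, 0.3)
  got <- zprojectMax(stk, 1)
  for (iy in 1:5) for (ix in 1:7) {
    expect_equal(got[iy, ix], max(arr[iy, ix, ]))
  }
})

test_that("YZ reslicing picks the nearest x index and matches direct slicing", {
  # stack whose value equals its x index
  arr <- array(0, c(6, 20, 3))
  for (ix in 1:20) arr[, ix, ] <- ix
  stk <- imageStack(arr, pixelXY = 0.05, zStep = 0.05)
  pl <- resliceYZ(stk, 1, c(0.125, 0.375, 0.625))
  expect_true(all(pl[[1]] == 3))  # positions spaced 0.25 um advance 5 px
  expect_true(all(pl[[2]] == 8))
  expect_true(all(pl[[3]] == 13))
  expect_equal(attr(pl[[1]], "pixelDims"), c(0.05, 0.05))

  set.seed(3)
  arr2 <- array(runif(6 * 20 * 3), c(6, 20, 3))
  stk2 <- imageStack(arr2, 0.05, 0.05)
  pl2 <- resliceYZ(stk2, 1, 0.425)
  expect_equal(unclass(pl2[[1]])[1:6, 1:3], arr2[, 9, ], ignore_attr = TRUE)

  expect_error(resliceYZ(stk, 1, 7.3), "7.3")
})

test_that("background estimation is the masked mean and rejects overlap", {
  img <- matrix(7, 8, 8)
  bg <- regionMask(matrix(TRUE, 8, 8), 0.1)
  expect_equal(estimateBackground(img, bg), 7)

  img2 <- matrix(3, 8, 8); img2[1:4, ] <- 9
  lvl3 <- regionMask(rbind(matrix(FALSE, 4, 8), matrix(TRUE, 4, 8)), 0.1)
  expect_equal(estimateBackground(img2, lvl3), 3)

  set.seed(4)
  img3 <- matrix(runif(64), 8)
  m <- matrix(runif(64) > 0.5, 8)
  expect_equal(estimateBackground(img3, regionMask(m, 0.1)),
               mean(img3[m]))

  cell <- regionMask(matrix(TRUE, 8, 8), 0.1)
  expect_error(estimateBackground(img, bg, cell), "overlaps")
})

test_that("stacks round-trip through TIFF files with metadata intact", {
  set.seed(6)
  stk <- imageStack(array(runif(4 * 5 * 3 * 2, 0, 12), c(4, 5, 3, 2)),
                    pixelXY = 0.05, zStep = 0.3,
                    channelNames = c("target", "ncad"))
  prefix <- file.path(withr::local_tempdir(), "stack")
  writeImageStack(stk, prefix)
  back <- readImageStack(prefix)
  expect_equal(voxels(back), voxels(stk), tolerance = 1e-6)
  expect_equal(pixelSizeXY(back), 0.05)
  expect_equal(zStepUm(back), 0.3)
  expect_equal(channelNames(back), c("target", "ncad"))
})

test_that("area bookkeeping is exact and class validity is enforced", {
  m <- regionMask(matrix(c(TRUE, FALSE, TRUE, TRUE), 2), c(0.1, 0.2))
  expect_equal(maskArea(m), 3 * 0.1 * 0.2)
  expect_error(imageStack(array(1, c(2, 2, 1, 1)), pixelXY = -1, zStep = 0.3),
               "positive")
  expect_error(getChannel(imageStack(array(1, c(2, 2, 1, 1)), 0.1, 0.3),
                          "nope"), "unknown channel")
})
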