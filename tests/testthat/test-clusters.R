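# Cluster segmentation against forced arithmetic and a flood-fill oracle.

test_that("segmentation arithmetic is forced by the geometry", {
  roi <- regionMask(matrix(TRUE, 100, 100), 0.05)

  blank <- matrix(0, 100, 100)
  expect_warning(cs0 <- segmentClusters(blank, roi, thresholdMethod = "fixed",
                                        fixedThreshold = 1), "no foreground")
  expect_equal(nClusters(cs0), 0)
  expect_equal(clusterStats(cs0)$densityPct, 0)

  # one 8x8 square at 50 nm/pixel: area 0.16 um^2, density 0.64 %
  img <- blank; img[20:27, 30:37] <- 10
  cs1 <- segmentClusters(img, roi, thresholdMethod = "fixed",
                         fixedThreshold = 5)
  expect_equal(nClusters(cs1), 1)
  st <- clusterStats(cs1)
  expect_equal(st$meanSizeUm2, 0.16)
  expect_equal(st$densityPct, 0.64)
})

test_that("labels equal an independent flood-fill oracle on random fields", {
  set.seed(21)
  for (i in 1:5) {
    img <- matrix(0, 40, 40)
    for (k in 1:8) {
      cy <- sample(5:35, 1); cx <- sample(5:35, 1); r <- runif(1, 1, 3)
      yy <- matrix(1:40, 40, 40); xx <- t(yy)
      img[(yy - cy)^2 + (xx - cx)^2 <= r^2] <- 10
    }
    roi <- regionMask(matrix(TRUE, 40, 40), 0.05)
    cs <- segmentClusters(img, roi, thresholdMethod = "fixed",
                          fixedThreshold = 5, minSizePx = 1)
    oracle <- floodLabel(img >= 5)
    # same partition: label maps agree up to label permutation
    expect_equal(max(labelMap(cs)), max(oracle))
    for (lb in seq_len(max(oracle))) {
      got <- unique(labelMap(cs)[oracle == lb])
      expect_length(got, 1)
    }
  }
})

test_that("cluster statistics match their definitions", {
  roi <- regionMask(matrix(TRUE, 60, 60), 0.05)
  img <- matrix(0, 60, 60)
  img[10:17, 10:17] <- 7       # 64 px = 0.16 um^2
  img[30:45, 30:37] <- 7       # 128 px = 0.32 um^2
  cs <- segmentClusters(img, roi, thresholdMethod = "fixed",
                        fixedThreshold = 3)
  st <- clusterStats(cs, background = 2)
  expect_equal(st$meanSizeUm2, 0.24)
  expect_equal(st$meanIntensity, 5)   # uniform b + c with background b
  expect_equal(st$rawMeanIntensity, 7)

  # per-pixel accumulation oracle on a random fixture
  set.seed(8)
  img2 <- matrix(runif(3600), 60)
  cs2 <- segmentClusters(img2, roi, thresholdMethod = "fixed",
                         fixedThreshold = 0.8, minSizePx = 1)
  lab <- labelMap(cs2)
  fgPx <- lab > 0
  expect_equal(clusterStats(cs2)$rawMeanIntensity, mean(img2[fgPx]))
  expect_equal(clusterStats(cs2)$densityPct, 100 * sum(fgPx) / 3600)
  expect_error(clusterStats(cs2, background = -1), ">= 0")
})

test_that("density is threshold-scale invariant and min-size monotone", {
  set.seed(31)
  ph <- makeMyocyteStack(tinyClusterSpec(seed = 3))
  tr <- ph$truth
  surf <- getChannel(ph$stack, "target")[, , tr$surfaceZ]
  d1 <- clusterStats(segmentClusters(surf, tr$cellMask))$densityPct
  d2 <- clusterStats(segmentClusters(surf * 3.7, tr$cellMask))$densityPct
  expect_equal(d1, d2, tolerance = 1e-12)

  nAt <- function(ms) nClusters(segmentClusters(surf, tr$cellMask,
                                                minSizePx = ms))
  sizes <- vapply(c(1L, 4L, 20L, 100L), nAt, integer(1))
  expect_true(all(diff(sizes) <= 0))

  # total cluster area never exceeds the ROI area
  st <- clusterStats(segmentClusters(surf, tr$cellMask))
  expect_lte(st$densityPct, 100)
})

test_that("en-face ICD profile recovers planted clusters and flags missing planes", {
  fx <- enFaceClusterStack()
  xUm <- (fx$xIndex - 0.5) * fx$px
  prof <- icdClusterProfile(fx$stack, xPositionsUm = c(xUm, 0.2),
                            thresholdMethod = "fixed", fixedThreshold = 2)
  roiPx <- sum(fx$icdPlane)
  expect_equal(prof$nClusters[1], fx$nSquares)
  expect_equal(prof$densityPct[1], 100 * fx$clusterPx / roiPx)
  expect_equal(prof$meanSizeUm2[1], fx$side^2 * fx$px^2)
  # plane without marker signal is reported missing, not fatal
  expect_true(is.na(prof$densityPct[2]))
  expect_error(icdClusterProfile(fx$stack, xPositionsUm = numeric(0)),
               "at least one")
})

test_that("occupancy equals the cluster density on the same inputs", {
  set.seed(12)
  img <- matrix(runif(2500), 50)
  region <- regionMask(matrix(TRUE, 50, 50), 0.1)
  expect_equal(occupancyPct(img, region, thresholdMethod = "fixed",
                            fixedThreshold = 0.7, minSizePx = 1),
               clusterStats(segmentClusters(img, region,
                                            thresholdMethod = "fixed",
                                            fixedThreshold = 0.7,
                                            minSizePx = 1))$densityPct)
  expect_warning(o <- occupancyPct(img, region, thresholdMethod = "fixed",
                                   fixedThreshold = -1), "entire ROI")
  expect_equal(o, 100)
  expect_warning(z <- occupancyPct(matrix(0, 50, 50), region), "foreground")
  expect_equal(z, 0)
})
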