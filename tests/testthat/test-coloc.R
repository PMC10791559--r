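# Pearson colocalization and Costes automatic thresholds.

twoPopulation <- function(n = 10000, fgFrac = 0.1, seed = 99) {
  set.seed(seed)
  nBg <- round(n * (1 - fgFrac)); nFg <- n - nBg
  fg <- runif(nFg, 100, 200)
  a <- matrix(c(runif(nBg, 0, 50), fg), 100)
  b <- matrix(c(runif(nBg, 0, 50), fg + rnorm(nFg, 0, 5)), 100)
  list(a = a, b = b)
}

test_that("Pearson correlation hits its exact limits", {
  set.seed(41)
  a <- matrix(runif(400), 20)
  expect_equal(pearsonCC(a, a), 1)
  expect_equal(pearsonCC(a, 7 - a), -1)
  b <- matrix(runif(10000), 100)
  c2 <- matrix(runif(10000), 100)
  expect_lte(abs(pearsonCC(b, c2)), 0.03)   # 3/sqrt(n) bound
  expect_error(pearsonCC(a, matrix(1, 20, 20)), "zero variance")
})

test_that("Costes thresholds match an exhaustive threshold-scan oracle", {
  tp <- twoPopulation()
  ct <- costesThresholds(tp$a, tp$b, tol = 0.5)
  expect_false(ct$undefined)
  expect_gt(ct$slope, 0)

  av <- as.numeric(tp$a); bv <- as.numeric(tp$b)
  oracle <- NA_real_
  for (T in sort(unique(av), decreasing = TRUE)) {
    sel <- av < T & bv < ct$slope * T + ct$intercept
    p <- if (sum(sel) >= 2 && sd(av[sel]) > 0 && sd(bv[sel]) > 0) {
      cor(av[sel], bv[sel])
    } else NA_real_
    if (is.na(p) || p <= 0) { oracle <- T; break }
  }
  # the bisection estimate brackets the oracle's first crossing
  expect_lt(abs(ct$Ta - oracle), 1)
  # the threshold separates the two planted populations
  expect_gt(ct$Ta, 50); expect_lt(ct$Ta, 110)
})

test_that("bisection contract: halving the tolerance moves Ta by less than tol", {
  tp <- twoPopulation(seed = 7)
  t1 <- costesThresholds(tp$a, tp$b, tol = 0.5)$Ta
  t2 <- costesThresholds(tp$a, tp$b, tol = 0.25)$Ta
  expect_lt(abs(t1 - t2), 0.5)
})

test_that("identical channels colocalize fully with a minimal threshold", {
  set.seed(42)
  a <- matrix(runif(2500, 1, 9), 50)
  r <- thresholdedPCC(a, a)
  expect_equal(r$pccAll, 1)
  expect_equal(r$pccAboveThreshold, 1)
  expect_lt(r$thresholdA, min(a) + 0.5)   # Ta -> min intensity
})

test_that("anti-correlated channels are flagged threshold-undefined", {
  set.seed(43)
  a <- matrix(runif(900), 30)
  expect_warning(r <- thresholdedPCC(a, 5 - a), "undefined")
  expect_true(is.na(r$pccAboveThreshold))
  expect_equal(r$pccAll, -1)
})

test_that("thresholded PCC is symmetric and affine-invariant", {
  tp <- twoPopulation(seed = 13)
  r1 <- thresholdedPCC(tp$a, tp$b)
  r2 <- thresholdedPCC(tp$b, tp$a)
  expect_equal(r1$pccAboveThreshold, r2$pccAboveThreshold, tolerance = 0.02)
  r3 <- thresholdedPCC(2.5 * tp$a + 10, tp$b)
  expect_equal(r1$pccAll, r3$pccAll, tolerance = 1e-12)
  expect_equal(r1$pccAboveThreshold, r3$pccAboveThreshold, tolerance = 0.02)
})

test_that("PCC decreases strictly as planted co-clusters are displaced", {
  ph <- makeMyocyteStack(tinyClusterSpec(clusterDensityPct = 6,
                                         applyPsf = TRUE, applyNoise = TRUE,
                                         seed = 17))
  surf <- getChannel(ph$stack, "target")[, , ph$truth$surfaceZ]
  shiftCols <- function(m, k) {
    if (k == 0) return(m)
    cbind(m[, (k + 1):ncol(m)], m[, 1:k])
  }
  # 50-nm pixels: 0.25 um = 5 px, 1 um = 20 px
  p0 <- pearsonCC(surf, shiftCols(surf, 0))
  p5 <- pearsonCC(surf, shiftCols(surf, 5))
  p20 <- pearsonCC(surf, shiftCols(surf, 20))
  expect_gt(p0, p5)
  expect_gt(p5, p20)
})

test_that("independent phantoms give near-zero thresholded PCC", {
  mk <- function(s) {
    ph <- makeMyocyteStack(tinyClusterSpec(clusterDensityPct = 6,
                                           applyPsf = TRUE,
                                           applyNoise = TRUE, seed = s))
    list(img = getChannel(ph$stack, "target")[, , ph$truth$surfaceZ],
         cell = ph$truth$cellMask)
  }
  a <- mk(11); b <- mk(77)
  r <- thresholdedPCC(a$img, b$img, mask = a$cell)
  expect_lte(abs(r$pccAboveThreshold), 0.05)
  expect_lte(abs(r$pccAll), 0.05)
  expect_gt(r$nPixelsUsed, 1e4)
})
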