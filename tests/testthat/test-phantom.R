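# Phantom generators: determinism, degenerate cases, noise statistics.

test_that("image phantom is deterministic and honors degenerate settings", {
  s <- tinySpec(seed = 7, clusterDensityPct = 3, applyNoise = TRUE)
  a <- makeMyocyteStack(s)
  b <- makeMyocyteStack(s)
  expect_identical(voxels(a$stack), voxels(b$stack))

  # no clusters, optics and noise off -> empty cluster table, deterministic
  # geometry
  d <- makeMyocyteStack(tinySpec(clusterDensityPct = 0))
  expect_equal(nrow(d$truth$clusterTable), 0)
  expect_identical(voxels(d$stack),
                   voxels(makeMyocyteStack(tinySpec(clusterDensityPct = 0))$stack))

  # no enrichment -> rim and interior means agree
  u <- makeMyocyteStack(tinySpec(lateralEnrichment = 1, icdEnrichment = 1))
  plane <- getChannel(u$stack, "target")[, , u$truth$centralZ]
  rim <- maskValues(u$truth$rimMask)
  interior <- maskValues(u$truth$cellMask) & !rim
  expect_equal(mean(plane[rim]), mean(plane[interior]), tolerance = 1e-9)
})

test_that("phantom truth masks are mutually consistent", {
  ph <- makeMyocyteStack(tinySpec(clusterDensityPct = 4, icdEnrichment = 2))
  tr <- ph$truth
  cell <- maskValues(tr$cellMask)
  expect_true(all(cell[maskValues(tr$rimMask)]))
  expect_true(all(cell[maskValues(tr$icdMask)]))
  expect_false(any(maskValues(tr$bgMask) & cell))
  # cluster centers lie inside the cell footprint
  px <- pixelSizeXY(ph$stack)
  for (i in seq_len(nrow(tr$clusterTable))) {
    iy <- ceiling(tr$clusterTable$cy[i] / px)
    ix <- ceiling(tr$clusterTable$cx[i] / px)
    expect_true(cell[iy, ix])
  }
})

test_that("phantom rejects impossible geometry and parameters", {
  expect_error(phantomSpec(frameLengthUm = 10, cellLengthUm = 30,
                           cellWidthUm = 12), "fit")
  expect_error(phantomSpec(photonScale = 0), "photonScale")
  expect_error(phantomSpec(clusterDensityPct = 120), "\\[0, 100\\]")
  expect_error(phantomSpec(lateralEnrichment = -1), ">= 0")
  # enrichment impossible for the rim area fraction
  expect_error(makeMyocyteStack(tinySpec(lateralEnrichment = 50)),
               "too large|not attainable")
})

test_that("Poisson-Gaussian noise has the predicted variance on a uniform region", {
  s <- tinySpec(applyNoise = TRUE, photonScale = 50, readNoiseSd = 0.05,
                background = 1, seed = 9)
  ph <- makeMyocyteStack(s)
  bg <- maskValues(ph$truth$bgMask)
  vals <- getChannel(ph$stack, "target")[, , 1][bg]
  expect_gt(length(vals), 1e4)
  predicted <- 1 / 50 + 0.05^2
  expect_lt(abs(var(vals) - predicted) / predicted, 0.1)
})

test_that("FRAP generator reproduces its construction exactly", {
  sp <- frapSimSpec(noiseSd = 0, backgroundBleachRate = 0)
  tr <- makeFrapDataset(sp)
  expect_equal(length(traceValues(tr$roi1)), 300)
  # reference constant; first post-bleach value is the bleach depth
  expect_true(all(traceValues(tr$roi3) == 1))
  expect_equal(traceValues(tr$roi1)[26], sp$bleachDepth)

  # immobile case: flat at the bleach depth
  im <- makeFrapDataset(frapSimSpec(A1 = 0, A2 = 0, noiseSd = 0,
                                    backgroundBleachRate = 0))
  expect_true(all(traceValues(im$roi1)[26:300] == im$roi1@values[26]))

  expect_error(frapSimSpec(A1 = 0.7, A2 = 0.5), "exceed 1")
  expect_error(frapSimSpec(tau1 = 60, tau2 = 5), "tau1")

  # determinism
  s2 <- frapSimSpec(noiseSd = 0.05, seed = 3)
  expect_identical(traceValues(makeFrapDataset(s2)$roi2),
                   traceValues(makeFrapDataset(s2)$roi2))
})

test_that("current simulator obeys driving-force sign and protocol shape", {
  sp <- inaSimSpec(nRepeats = 1, sweepNoiseSd = 0, pulseMs = 10)
  fam <- makeInaDataset(sp)
  expect_equal(testVoltages(fam), seq(-100, 75, by = 5))
  # single noiseless repeat: ensemble equals the sweep
  expect_equal(ensembleAverage(fam), fam@current[, , 1])
  # at and above the reversal potential the current is never inward
  above <- testVoltages(fam) >= sp$eRev
  expect_true(all(fam@current[, above, ] >= 0))
  expect_error(inaSimSpec(nRepeats = 0), "nRepeats")
})

test_that("band-table generator round-trips true ratios at zero noise", {
  tab <- makeBandTable(c(EB1 = 1.5), laneNoiseCv = 0, nExperiments = 3)
  r <- suppressMessages(ratioPkaCon(tab, "EB1"))
  expect_equal(r$summary$mean, 1.5)
  expect_equal(r$perExperiment$ratio, rep(1.5, 3))

  tabU <- makeBandTable(c(a = 1, b = 1), laneNoiseCv = 0, scheme = "coip")
  expect_equal(coipDegree(tabU, "a")$summary$mean, 1)
  expect_equal(surfaceDegree(
    makeBandTable(c(x = 1), laneNoiseCv = 0, scheme = "surface"),
    "x")$summary$mean, 1)

  expect_error(makeBandTable(c(a = 1.5), laneNoiseCv = -0.1), ">= 0")
  expect_error(makeBandTable(c(a = -2)), "positive")
})
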