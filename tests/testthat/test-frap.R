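# FRAP correction, normalization, biexponential fitting.

test_that("bleach correction divides out the reference decline", {
  n <- 300
  flat <- frapTrace(rep(2, n), 3)
  target <- frapTrace(runif(n, 1, 3), 1)
  expect_equal(traceValues(bleachCorrect(target, flat)),
               traceValues(target))

  # reference decayed to 90 % at the last scan -> last value * 1/0.9
  ref <- frapTrace(c(rep(1, 25), seq(1, 0.9, length.out = n - 25)), 3)
  corr <- bleachCorrect(target, ref)
  expect_equal(traceValues(corr)[n], traceValues(target)[n] / 0.9)

  # simulated monoexponential background bleach is fully removed
  sp <- frapSimSpec(noiseSd = 0, backgroundBleachRate = 0.003)
  tr <- makeFrapDataset(sp)
  fixedRef <- bleachCorrect(tr$roi3, tr$roi3)
  expect_equal(max(abs(diff(traceValues(fixedRef)))), 0, tolerance = 1e-12)

  bad <- frapTrace(c(rep(1, 200), rep(-0.1, 100)), 3)
  expect_error(bleachCorrect(target, bad), "crosses zero")
  expect_error(bleachCorrect(target, frapTrace(rep(1, 10), 3, nPrebleach = 2)),
               "equal length")
})

test_that("normalization pins the bleach span to [0, 1]", {
  sp <- frapSimSpec(noiseSd = 0.01, seed = 5)
  tr <- makeFrapDataset(sp)$roi1
  n <- normalizeFrap(tr)
  expect_equal(traceValues(n)[25], 1)
  expect_equal(traceValues(n)[26], 0)

  flat <- frapTrace(c(rep(1, 25), rep(0.3, 275)), 1)
  nf <- normalizeFrap(flat)
  expect_true(all(traceValues(nf)[26:300] == 0))

  noBleach <- frapTrace(rep(1, 300), 1)
  expect_error(normalizeFrap(noBleach), "bleach")
})

test_that("noiseless biexponential truth is recovered to machine-level accuracy", {
  sp <- frapSimSpec(A1 = 0.3, tau1 = 5, A2 = 0.4, tau2 = 60,
                    noiseSd = 0, backgroundBleachRate = 0)
  fit <- fitBiexponential(normalizeFrap(makeFrapDataset(sp)$roi1))
  expect_equal(fit@A1, 0.3, tolerance = 1e-6)
  expect_equal(fit@tau1, 5, tolerance = 1e-6)
  expect_equal(fit@A2, 0.4, tolerance = 1e-6)
  expect_equal(fit@tau2, 60, tolerance = 1e-6)
  # closed-form recovery at 2 min
  closed <- 100 * (0.3 * (1 - exp(-120 / 5)) + 0.4 * (1 - exp(-120 / 60)))
  expect_equal(recovery2min(fit), closed, tolerance = 1e-6)
  expect_equal(mobileFraction(fit), 0.7, tolerance = 1e-6)
})

test_that("immobile and single-exponential limits are respected", {
  flat <- frapTrace(c(rep(1, 25), rep(0, 275)), 1)
  # already normalized by construction: bleach span 1 -> N = values
  fit0 <- fitBiexponential(normalizeFrap(frapTrace(c(rep(1, 25),
                                                     rep(0.2, 275)), 1)))
  expect_lte(mobileFraction(fit0), 1e-6)
  expect_equal(recovery2min(fit0), 0, tolerance = 1e-4)

  # single-exponential truth: no spurious second component
  t <- (0:274) * 0.5
  y <- 0.6 * (1 - exp(-t / 20))
  fit1 <- fitBiexponential(normalizeFrap(frapTrace(c(rep(1, 25), y), 1)))
  small <- min(fit1@A1, fit1@A2)
  expect_lte(small, 0.02)
  expect_equal(mobileFraction(fit1), 0.6, tolerance = 0.01)
})

test_that("the full pipeline is invariant to affine re-expression of intensities", {
  sp <- frapSimSpec(noiseSd = 0.01, backgroundBleachRate = 0.002,
                    bgOffset = 0, seed = 8)
  traces <- makeFrapDataset(sp)
  res1 <- analyzeFrap(traces, targetRoi = 1)
  scaled <- lapply(traces, function(tr) {
    frapTrace(3 * traceValues(tr) + 0, tr@roiId, tr@scanInterval,
              tr@nPrebleach)
  })
  res2 <- analyzeFrap(scaled, targetRoi = 1)
  expect_equal(traceValues(res1$normalized), traceValues(res2$normalized),
               tolerance = 1e-9)
  expect_equal(recovery2min(res1$fit), recovery2min(res2$fit),
               tolerance = 1e-6)
})

test_that("recovery at 2 min responds monotonically to the kinetic parameters", {
  mk <- function(A1, tau1, A2, tau2) {
    sp <- frapSimSpec(A1 = A1, tau1 = tau1, A2 = A2, tau2 = tau2,
                      noiseSd = 0, backgroundBleachRate = 0)
    recovery2min(fitBiexponential(normalizeFrap(makeFrapDataset(sp)$roi1)))
  }
  base <- mk(0.3, 5, 0.4, 60)
  expect_gt(mk(0.4, 5, 0.4, 60), base)      # larger amplitude
  expect_lt(mk(0.3, 5, 0.4, 300), base)     # slower component
})

test_that("traces round-trip through the long-format CSV", {
  sp <- frapSimSpec(noiseSd = 0.02, seed = 12)
  traces <- makeFrapDataset(sp)
  path <- file.path(withr::local_tempdir(), "frap.csv")
  writeFrapTable(traces, path)
  back <- readFrapTable(path)
  expect_equal(traceValues(back$roi2), traceValues(traces$roi2))
  expect_equal(back$roi3@roiId, 3L)
})
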