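# Synthetic FRAP acquisitions with known recovery kinetics.

#' Specification of a synthetic FRAP acquisition
#'
#' Parameters of the four-ROI FRAP emulation: ROI 1 (cell center) and ROI 2
#' (cell end) are photobleached and recover with the saturating biexponential
#' `A1 (1 - exp(-t/tau1)) + A2 (1 - exp(-t/tau2))` scaled to the bleached
#' span; ROI 3 (in-cell reference) carries only the monoexponential
#' acquisition-bleach decay; ROI 4 (cell-free) is a constant offset. The
#' acquisition grid follows the standard protocol: 25 baseline scans, the
#' bleach, then 275 recovery scans at 0.5 s intervals.
#'
#' @param A1,A2 fractional recovery amplitudes, `>= 0`, `A1 + A2 <= 1`.
#' @param tau1,tau2 recovery time constants, s, `tau1 < tau2`.
#' @param bleachDepth fluorescence immediately after the bleach as a fraction
#'   of the baseline, in `(0, 1)` (the protocol bleaches to < 30%).
#' @param backgroundBleachRate monoexponential acquisition-bleach rate, 1/s,
#'   applied to ROIs 1-3.
#' @param noiseSd Gaussian noise s.d. added to every scan of every ROI.
#' @param bgOffset constant background level (ROI 4), added to all ROIs.
#' @param nPrebleach,nPostbleach scan counts before/after the bleach.
#' @param scanInterval seconds between scans.
#' @param seed integer RNG seed.
#' @return a `FRAPSimSpec` (validated list).
#' @seealso [makeFrapDataset()], [fitBiexponential()]
#' @export
frapSimSpec <- function(A1 = 0.3, A2 = 0.4, tau1 = 5, tau2 = 60,
                        bleachDepth = 0.25, backgroundBleachRate = 0.001,
                        noiseSd = 0.02, bgOffset = 0,
                        nPrebleach = 25L, nPostbleach = 275L,
                        scanInterval = 0.5, seed = 1L) {
  if (A1 < 0 || A2 < 0) stop("amplitudes must be >= 0")
  if (A1 + A2 > 1) stop("A1 + A2 must not exceed 1 (mobile fraction)")
  if (tau1 <= 0 || tau2 <= 0) stop("time constants must be positive")
  if (tau1 >= tau2) stop("tau1 must be smaller than tau2")
  if (bleachDepth <= 0 || bleachDepth >= 1) {
    stop("bleachDepth must be in (0, 1)")
  }
  if (backgroundBleachRate < 0) stop("backgroundBleachRate must be >= 0")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  structure(list(
    A1 = A1, A2 = A2, tau1 = tau1, tau2 = tau2,
    bleachDepth = bleachDepth, backgroundBleachRate = backgroundBleachRate,
    noiseSd = noiseSd, bgOffset = bgOffset,
    nPrebleach = as.integer(nPrebleach),
    nPostbleach = as.integer(nPostbleach),
    scanInterval = scanInterval, seed = as.integer(seed)
  ), class = "FRAPSimSpec")
}

#' Generate a four-ROI synthetic FRAP dataset
#'
#' @param spec a [frapSimSpec()].
#' @return named list of four [FRAPTrace-class] objects (`roi1` center,
#'   `roi2` end, `roi3` reference, `roi4` background).
#' @examples
#' traces <- makeFrapDataset(frapSimSpec(noiseSd = 0))
#' traceValues(traces$roi1)[26]  # == bleachDepth
#' @export
makeFrapDataset <- function(spec) {
  stopifnot(inherits(spec, "FRAPSimSpec"))
  n <- spec$nPrebleach + spec$nPostbleach
  tAll <- (seq_len(n) - 1) * spec$scanInterval
  decay <- exp(-spec$backgroundBleachRate * tAll)
  post <- (spec$nPrebleach + 1L):n
  tPost <- (seq_along(post) - 1L) * spec$scanInterval

  recov <- spec$A1 * (1 - exp(-tPost / spec$tau1)) +
    spec$A2 * (1 - exp(-tPost / spec$tau2))
  bleached <- rep(1, n)
  bleached[post] <- spec$bleachDepth + (1 - spec$bleachDepth) * recov

  base <- list(
    roi1 = bleached * decay,
    roi2 = bleached * decay,
    roi3 = decay,
    roi4 = rep(0, n)
  )
  withSeed(spec$seed, {
    out <- lapply(seq_along(base), function(i) {
      v <- base[[i]] + spec$bgOffset
      if (spec$noiseSd > 0) v <- v + stats::rnorm(n, 0, spec$noiseSd)
      frapTrace(v, roiId = i, scanInterval = spec$scanInterval,
                nPrebleach = spec$nPrebleach)
    })
    names(out) <- names(base)
    out
  })
}
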