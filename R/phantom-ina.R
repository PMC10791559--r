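# Synthetic cell-attached sodium-current sweep families.

#' Specification of a synthetic sodium-current recording
#'
#' Hodgkin-Huxley-style inward current for a cell-attached patch protocol.
#' Voltages are membrane potentials (the acquisition protocol steps the
#' pipette from +120 mV holding to +100..-75 mV in -5 mV increments; with
#' the resting potential zeroed this corresponds to membrane test voltages
#' -100..+75 mV in +5 mV steps). Per test voltage `V` the noiseless current
#' during the pulse is
#' `I(t) = gmax * minf(V)^3 * (1 - exp(-t/tauAct))^3 * exp(-t/tauInact) * (V - eRev)`
#' with `minf(V) = 1 / (1 + exp(-(V - vHalfAct)/kAct))`, which is inward
#' (negative) for test voltages below the reversal potential. Gaussian sweep
#' noise is added independently per repeat.
#'
#' @param gmax conductance scale, nS (peak currents in pA).
#' @param vHalfAct,kAct Boltzmann activation midpoint and slope, mV.
#' @param eRev reversal potential, mV.
#' @param tauActMs,tauInactMs activation/inactivation time constants, ms;
#'   either scalars or functions of voltage.
#' @param sweepNoiseSd Gaussian noise s.d. per sample, pA.
#' @param nRepeats number of protocol repeats (the acquisition used 4-12).
#' @param vStart,vStop,vStep membrane test-voltage ladder, mV.
#' @param pulseMs test-pulse duration, ms.
#' @param prePulseMs pre-pulse baseline recorded before the step, ms.
#' @param dtMs sampling interval, ms.
#' @param seed integer RNG seed.
#' @return an `INaSimSpec` (validated list).
#' @seealso [makeInaDataset()], [designedPeakVoltage()]
#' @export
inaSimSpec <- function(gmax = 1, vHalfAct = -52, kAct = 3.5, eRev = 65,
                       tauActMs = 0.15, tauInactMs = 1.5,
                       sweepNoiseSd = 0, nRepeats = 6L,
                       vStart = -100, vStop = 75, vStep = 5,
                       pulseMs = 200, prePulseMs = 5, dtMs = 0.05,
                       seed = 1L) {
  if (nRepeats < 1L) stop("nRepeats must be >= 1")
  if (gmax <= 0) stop("gmax must be positive")
  if (kAct <= 0) stop("kAct must be positive")
  if (sweepNoiseSd < 0) stop("sweepNoiseSd must be >= 0")
  if (pulseMs <= 0 || dtMs <= 0 || prePulseMs < 0) {
    stop("pulse/sampling times must be positive")
  }
  if (vStep == 0 || (vStart != vStop && sign(vStop - vStart) != sign(vStep))) {
    stop("voltage ladder direction must match vStep")
  }
  structure(list(
    gmax = gmax, vHalfAct = vHalfAct, kAct = kAct, eRev = eRev,
    tauActMs = tauActMs, tauInactMs = tauInactMs,
    sweepNoiseSd = sweepNoiseSd, nRepeats = as.integer(nRepeats),
    vStart = vStart, vStop = vStop, vStep = vStep,
    pulseMs = pulseMs, prePulseMs = prePulseMs, dtMs = dtMs,
    seed = as.integer(seed)
  ), class = "INaSimSpec")
}

inaTauAt <- function(tau, v) if (is.function(tau)) tau(v) else tau

# Noiseless pulse-phase current at voltage v over times t (ms since pulse
# onset).
inaModelCurrent <- function(spec, v, t) {
  minf <- 1 / (1 + exp(-(v - spec$vHalfAct) / spec$kAct))
  ta <- inaTauAt(spec$tauActMs, v)
  ti <- inaTauAt(spec$tauInactMs, v)
  spec$gmax * minf^3 * (1 - exp(-t / ta))^3 * exp(-t / ti) * (v - spec$eRev)
}

#' Voltage of maximal peak inward current by exhaustive ladder scan
#'
#' Brute-force scan of the noiseless model over the protocol ladder: the
#' designed peak voltage that a correct peak detector must identify.
#'
#' @param spec an [inaSimSpec()].
#' @return voltage (mV) with the largest-magnitude inward peak.
#' @export
designedPeakVoltage <- function(spec) {
  volts <- seq(spec$vStart, spec$vStop, by = spec$vStep)
  t <- seq(0, spec$pulseMs, by = spec$dtMs)
  peaks <- vapply(volts, function(v) {
    i <- inaModelCurrent(spec, v, t)
    -min(c(i, 0))
  }, numeric(1))
  volts[which.max(peaks)]
}

#' Generate a synthetic sweep family
#'
#' @param spec an [inaSimSpec()].
#' @return a [SweepFamily-class] of dimensions
#'   `(time, voltage, repeat)` with the pre-pulse baseline at zero current.
#' @examples
#' fam <- makeInaDataset(inaSimSpec(nRepeats = 2, pulseMs = 10))
#' dim(sweepCurrents(fam))
#' @export
makeInaDataset <- function(spec) {
  stopifnot(inherits(spec, "INaSimSpec"))
  volts <- seq(spec$vStart, spec$vStop, by = spec$vStep)
  nPre <- round(spec$prePulseMs / spec$dtMs)
  tPulse <- seq(0, spec$pulseMs - spec$dtMs, by = spec$dtMs)
  nT <- nPre + length(tPulse)
  base <- array(0, c(nT, length(volts)))
  for (vi in seq_along(volts)) {
    base[(nPre + 1L):nT, vi] <- inaModelCurrent(spec, volts[vi], tPulse)
  }
  cur <- withSeed(spec$seed, {
    out <- array(0, c(nT, length(volts), spec$nRepeats))
    for (ri in seq_len(spec$nRepeats)) {
      noise <- if (spec$sweepNoiseSd > 0) {
        array(stats::rnorm(length(base), 0, spec$sweepNoiseSd), dim(base))
      } else 0
      out[, , ri] <- base + noise
    }
    out
  })
  sweepFamily(cur, timeStepMs = spec$dtMs, voltages = volts,
              pulseStart = nPre + 1L)
}
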