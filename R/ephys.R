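# Ensemble-current analysis: maximal peak inward current and its
# inactivation time constant.

#' Construct a SweepFamily
#'
#' @param current numeric array `(time, voltage, repeat)`, pA, inward
#'   negative; a matrix is treated as a single repeat.
#' @param timeStepMs sampling interval, ms.
#' @param voltages test-voltage ladder, mV, strictly monotone.
#' @param pulseStart index of the first test-pulse sample.
#' @return a [SweepFamily-class].
#' @export
sweepFamily <- function(current, timeStepMs, voltages, pulseStart = 1L) {
  if (length(dim(current)) == 2L) {
    current <- array(current, c(dim(current), 1L))
  }
  new("SweepFamily", current = current, timeStepMs = timeStepMs,
      voltages = as.numeric(voltages), pulseStart = as.integer(pulseStart))
}

#' Ensemble average of a sweep family
#'
#' Arithmetic mean over repeats per voltage and time point -- the ensemble
#' current of a patch, smoothing stochastic channel openings.
#'
#' @param family a [SweepFamily-class].
#' @return numeric matrix `(time, voltage)`.
#' @export
ensembleAverage <- function(family) {
  stopifnot(is(family, "SweepFamily"))
  d <- dim(family@current)
  rowSums(family@current, dims = 2L) / d[3]
}

#' Maximal peak inward current across the voltage ladder
#'
#' Per test voltage, the most negative ensemble current within the pulse
#' window after per-voltage baseline subtraction (mean of the `baselineMs`
#' preceding the pulse) and after blanking the first `blankMs` of the pulse
#' (residual capacitive transient). The maximal peak is the largest
#' magnitude across voltages; all-outward families yield amplitude 0 with a
#' warning.
#'
#' @param ensemble `(time, voltage)` matrix from [ensembleAverage()].
#' @param voltages test-voltage ladder, mV.
#' @param timeStepMs sampling interval, ms.
#' @param pulseStart index of the first pulse sample.
#' @param blankMs capacitive blanking interval at pulse onset, ms.
#' @param baselineMs pre-pulse baseline window, ms.
#' @return list: `peakAmplitudePa` (magnitude, >= 0), `peakVoltageMv`,
#'   `peakTimeMs` (since pulse onset), `perVoltage` data.frame.
#' @export
peakIna <- function(ensemble, voltages, timeStepMs, pulseStart = 1L,
                    blankMs = 0.3, baselineMs = 5) {
  stopifnot(ncol(ensemble) == length(voltages))
  blankN <- round(blankMs / timeStepMs)
  w0 <- pulseStart + blankN
  if (w0 > nrow(ensemble)) stop("empty pulse window after blanking")
  basN <- min(pulseStart - 1L, round(baselineMs / timeStepMs))
  per <- lapply(seq_along(voltages), function(vi) {
    tr <- ensemble[, vi]
    if (basN > 0L) tr <- tr - mean(tr[(pulseStart - basN):(pulseStart - 1L)])
    win <- tr[w0:length(tr)]
    i <- which.min(win)
    data.frame(voltageMv = voltages[vi],
               peakPa = min(win),
               peakTimeMs = (w0 - pulseStart + i - 1L) * timeStepMs)
  })
  per <- do.call(rbind, per)
  inward <- per$peakPa < 0
  if (!any(inward)) {
    warning("no inward current at any test voltage")
    return(list(peakAmplitudePa = 0, peakVoltageMv = NA_real_,
                peakTimeMs = NA_real_, perVoltage = per))
  }
  best <- which.min(per$peakPa)
  list(peakAmplitudePa = -per$peakPa[best],
       peakVoltageMv = per$voltageMv[best],
       peakTimeMs = per$peakTimeMs[best],
       perVoltage = per)
}

#' Inactivation time constant of an ensemble trace
#'
#' Fits the monoexponential decay
#' `I(t) = Ipeak exp(-(t - t0)/tau) + c` from shortly after the current peak
#' to the window end; the offset `c` absorbs residual leak. The fit window
#' starts `startDelayMs` after the peak so that the tail of the activation
#' phase does not contaminate the decay estimate (the window bounds are
#' configurable and recorded by callers). A non-decaying trace yields `NA`
#' with diagnostics.
#'
#' @param trace ensemble current at one voltage (numeric vector over the
#'   pulse window, baseline-subtracted).
#' @param timeStepMs sampling interval, ms.
#' @param peakIndex optional index of the peak; defaults to the most
#'   negative sample.
#' @param startDelayMs delay between the peak and the first fitted sample,
#'   ms.
#' @return list with `tauInactMs`, `offset`, `rss`, or `NA` fields plus
#'   `reason` when the fit is undefined.
#' @export
fitInactivation <- function(trace, timeStepMs, peakIndex = NULL,
                            startDelayMs = 0.5) {
  if (is.null(peakIndex)) peakIndex <- which.min(trace)
  if (length(trace) - peakIndex < 10L) {
    stop("need at least 10 samples after the peak")
  }
  start <- max(peakIndex,
               min(peakIndex + round(startDelayMs / timeStepMs),
                   length(trace) - 10L))
  dec <- trace[start:length(trace)]
  miss <- list(tauInactMs = NA_real_, offset = NA_real_, rss = NA_real_)
  if (dec[1] >= 0) {
    miss$reason <- "no inward peak"
    return(miss)
  }
  tailLevel <- mean(utils::tail(dec, max(5L, length(dec) %/% 10L)))
  if (abs(tailLevel - dec[1]) < 0.05 * abs(dec[1])) {
    miss$reason <- "trace does not decay after the peak"
    return(miss)
  }
  t <- (seq_along(dec) - 1L) * timeStepMs
  # crude tau guess: time to decay to 1/e of the peak-to-tail span
  span <- dec[1] - tailLevel
  i1e <- which(dec - tailLevel >= span * exp(-1))[1]
  tau0 <- max(timeStepMs, (if (is.na(i1e)) 5L else i1e) * timeStepMs)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      dec ~ ip * exp(-t / tau) + c0,
      start = list(ip = span, tau = tau0, c0 = tailLevel),
      lower = c(-Inf, timeStepMs / 100, -Inf),
      control = minpack.lm::nls.lm.control(
        maxiter = 200, ftol = 1e-14, ptol = 1e-14)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    miss$reason <- "fit did not converge"
    return(miss)
  }
  cf <- stats::coef(fit)
  list(tauInactMs = unname(cf[["tau"]]), offset = unname(cf[["c0"]]),
       rss = sum(stats::residuals(fit)^2))
}

#' Per-patch sodium-current statistics
#'
#' Convenience wrapper: ensemble-average a sweep family, locate the maximal
#' peak inward current, and fit its inactivation time constant.
#'
#' @param family a [SweepFamily-class].
#' @param ... passed to [peakIna()].
#' @return list: `peakAmplitudePa`, `peakVoltageMv`, `tauInactMs`,
#'   `fitRss`, `perVoltage`.
#' @export
analyzeSweepFamily <- function(family, ...) {
  ens <- ensembleAverage(family)
  pk <- peakIna(ens, family@voltages, family@timeStepMs,
                pulseStart = family@pulseStart, ...)
  if (is.na(pk$peakVoltageMv)) {
    return(c(pk[c("peakAmplitudePa", "peakVoltageMv")],
             list(tauInactMs = NA_real_, fitRss = NA_real_,
                  perVoltage = pk$perVoltage)))
  }
  vi <- match(pk$peakVoltageMv, family@voltages)
  tr <- ens[, vi]
  basN <- min(family@pulseStart - 1L, round(5 / family@timeStepMs))
  if (basN > 0L) {
    tr <- tr - mean(tr[(family@pulseStart - basN):(family@pulseStart - 1L)])
  }
  win <- tr[family@pulseStart:length(tr)]
  tf <- fitInactivation(win, family@timeStepMs)
  list(peakAmplitudePa = pk$peakAmplitudePa,
       peakVoltageMv = pk$peakVoltageMv,
       tauInactMs = tf$tauInactMs, fitRss = tf$rss,
       perVoltage = pk$perVoltage)
}

#' Read a sweep family from a long-format table
#'
#' @param path CSV with columns `repeat.` (or `rep`), `voltage`, `time`,
#'   `current` (time in ms, current in pA).
#' @param pulseStartMs time at which the test pulse begins, ms.
#' @return a [SweepFamily-class].
#' @export
readSweepTable <- function(path, pulseStartMs = 0) {
  df <- utils::read.csv(path)
  repCol <- intersect(c("rep", "repeat.", "sweep"), names(df))[1]
  stopifnot(!is.na(repCol), all(c("voltage", "time", "current") %in% names(df)))
  reps <- sort(unique(df[[repCol]]))
  volts <- sort(unique(df$voltage))
  times <- sort(unique(df$time))
  arr <- array(NA_real_, c(length(times), length(volts), length(reps)))
  ti <- match(df$time, times)
  vi <- match(df$voltage, volts)
  ri <- match(df[[repCol]], reps)
  arr[cbind(ti, vi, ri)] <- df$current
  if (anyNA(arr)) stop("incomplete sweep table: missing (time, voltage, repeat) cells")
  dt <- if (length(times) > 1L) times[2] - times[1] else 1
  sweepFamily(arr, timeStepMs = dt, voltages = volts,
              pulseStart = max(1L, round(pulseStartMs / dt) + 1L))
}
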