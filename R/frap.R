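# FRAP trace correction, normalization and biexponential recovery fitting.

#' Construct a FRAPTrace
#'
#' @param values intensity per scan.
#' @param roiId ROI id 1-4 (1 center, 2 end, 3 reference, 4 background).
#' @param scanInterval seconds between scans.
#' @param nPrebleach number of baseline scans.
#' @return a [FRAPTrace-class].
#' @export
frapTrace <- function(values, roiId, scanInterval = 0.5, nPrebleach = 25L) {
  new("FRAPTrace", values = as.numeric(values), roiId = as.integer(roiId),
      scanInterval = scanInterval, nPrebleach = as.integer(nPrebleach))
}

withValues <- function(trace, values) {
  new("FRAPTrace", values = as.numeric(values), roiId = trace@roiId,
      scanInterval = trace@scanInterval, nPrebleach = trace@nPrebleach)
}

#' Subtract the cell-free background level from a trace
#'
#' The background ROI's mean intensity (a constant offset) is removed before
#' any bleach correction, so that the multiplicative reference correction
#' acts on true fluorescence.
#'
#' @param trace a [FRAPTrace-class].
#' @param background the ROI-4 [FRAPTrace-class], or a scalar level.
#' @return corrected [FRAPTrace-class].
#' @export
subtractBackground <- function(trace, background) {
  lvl <- if (is(background, "FRAPTrace")) mean(background@values)
         else as.numeric(background)
  withValues(trace, trace@values - lvl)
}

#' Correct acquisition bleaching against the reference ROI
#'
#' Divides the target trace by the reference ROI's fluorescence decline,
#' rescaled to the reference's pre-bleach mean:
#' `corrected(t) = target(t) * refPre / reference(t)`. A constant reference
#' leaves the target untouched.
#'
#' @param target bleached-ROI [FRAPTrace-class].
#' @param reference unbleached in-cell reference [FRAPTrace-class] (ROI 3);
#'   must be positive everywhere (after background subtraction).
#' @return corrected [FRAPTrace-class].
#' @export
bleachCorrect <- function(target, reference) {
  stopifnot(is(target, "FRAPTrace"), is(reference, "FRAPTrace"))
  if (length(target@values) != length(reference@values)) {
    stop("target and reference traces must have equal length")
  }
  if (any(reference@values <= 0)) {
    stop("reference trace crosses zero; background bleach correction undefined")
  }
  refPre <- mean(reference@values[seq_len(reference@nPrebleach)])
  withValues(target, target@values * refPre / reference@values)
}

#' Normalize a FRAP trace to the bleach span
#'
#' Maps the trace to `N(t) = (F(t) - F_post) / (F_pre - F_post)` where
#' `F_pre` is the scan right before photobleaching (scan 25 under the
#' default protocol) and `F_post` the first scan after it (scan 26), so
#' `N = 1` immediately before and `N = 0` immediately after the bleach.
#'
#' @param trace a [FRAPTrace-class].
#' @param prebleachMean use the mean of all baseline scans instead of the
#'   single last pre-bleach scan (robustness option, off by default).
#' @return normalized [FRAPTrace-class].
#' @export
normalizeFrap <- function(trace, prebleachMean = FALSE) {
  stopifnot(is(trace, "FRAPTrace"))
  i25 <- trace@nPrebleach
  fPre <- if (prebleachMean) mean(trace@values[seq_len(i25)])
          else trace@values[i25]
  fPost <- trace@values[i25 + 1L]
  if (fPre <= fPost) {
    stop("non-positive bleach span: photobleaching failed ",
         "(pre-bleach value must exceed the first post-bleach value)")
  }
  withValues(trace, (trace@values - fPost) / (fPre - fPost))
}

#' Fit the constrained biexponential recovery
#'
#' Least-squares fit of
#' `N(t) = A1 (1 - exp(-t/tau1)) + A2 (1 - exp(-t/tau2))` to the post-bleach
#' scans of a normalized trace (time zero at the first post-bleach scan, so
#' the fitted curve is anchored at `N(0) = 0`). Constraints: `A1, A2 >= 0`,
#' `0.1 s <= tau <= 1e4 s`, components ordered so `tau1 < tau2`. The fit is
#' multi-started from `nStarts` seeded initial points and the lowest
#' residual sum of squares wins. The plateau `A1 + A2` is the mobile
#' fraction; `recovery2min` is the fitted curve at 120 s, in percent.
#'
#' @param trace a normalized [FRAPTrace-class] with at least 20 post-bleach
#'   scans.
#' @param nStarts number of multi-start initial points (>= 1).
#' @param seed RNG seed for the start dispersion.
#' @return a [FRAPFit-class], or `NA` (with a warning) if no start
#'   converges.
#' @examples
#' spec <- frapSimSpec(noiseSd = 0, backgroundBleachRate = 0)
#' tr <- normalizeFrap(makeFrapDataset(spec)$roi1)
#' fitBiexponential(tr)
#' @export
fitBiexponential <- function(trace, nStarts = 5L, seed = 1L) {
  stopifnot(is(trace, "FRAPTrace"))
  post <- (trace@nPrebleach + 1L):length(trace@values)
  if (length(post) < 20L) stop("need at least 20 post-bleach points")
  t <- (seq_along(post) - 1L) * trace@scanInterval
  y <- trace@values[post]
  if (max(abs(y)) < 1e-10) {
    # immobile limit: nothing recovers, amplitudes are zero
    return(new("FRAPFit", A1 = 0, A2 = 0, tau1 = 0.1, tau2 = 1,
               rss = sum(y^2), recovery2min = 0))
  }

  starts <- withSeed(seed, {
    tauPairs <- rbind(
      c(5, 60), c(1, 30), c(0.5, 200), c(10, 300), c(2, 1000)
    )
    extra <- max(0L, nStarts - nrow(tauPairs))
    if (extra > 0L) {
      tauPairs <- rbind(tauPairs, cbind(
        exp(stats::runif(extra, log(0.2), log(50))),
        exp(stats::runif(extra, log(20), log(5000)))
      ))
    }
    tauPairs[seq_len(max(1L, nStarts)), , drop = FALSE]
  })
  plateau <- max(0.01, min(1.4, mean(utils::tail(y, 10L))))

  best <- NULL
  for (si in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A1 * (1 - exp(-t / tau1)) + A2 * (1 - exp(-t / tau2)),
        start = list(A1 = plateau / 2, A2 = plateau / 2,
                     tau1 = starts[si, 1], tau2 = starts[si, 2]),
        lower = c(0, 0, 0.1, 0.1), upper = c(1.5, 1.5, 1e4, 1e4),
        control = minpack.lm::nls.lm.control(
          maxiter = 200, ftol = 1e-12, ptol = 1e-12)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(coef = stats::coef(fit), rss = rss)
    }
  }
  if (is.null(best)) {
    warning("biexponential fit failed to converge from all starts")
    return(NA)
  }
  cf <- best$coef
  # order components by time constant
  if (cf[["tau1"]] > cf[["tau2"]]) {
    cf <- c(A1 = cf[["A2"]], A2 = cf[["A1"]],
            tau1 = cf[["tau2"]], tau2 = cf[["tau1"]])
  }
  if (cf[["A1"]] + cf[["A2"]] > 1) {
    message("fitted plateau exceeds 1 (mobile fraction > 100%): ",
            format(cf[["A1"]] + cf[["A2"]], digits = 4))
  }
  rec <- 100 * (cf[["A1"]] * (1 - exp(-120 / cf[["tau1"]])) +
                cf[["A2"]] * (1 - exp(-120 / cf[["tau2"]])))
  new("FRAPFit", A1 = unname(cf[["A1"]]), A2 = unname(cf[["A2"]]),
      tau1 = unname(cf[["tau1"]]), tau2 = unname(cf[["tau2"]]),
      rss = best$rss, recovery2min = rec)
}

#' Full FRAP analysis of a four-ROI acquisition
#'
#' Background subtraction (ROI 4), acquisition-bleach correction against the
#' reference (ROI 3), normalization to the bleach span and constrained
#' biexponential fitting, for one bleached ROI.
#'
#' @param traces named list of [FRAPTrace-class] (`roi1`..`roi4`) as
#'   returned by [makeFrapDataset()] or [readFrapTable()].
#' @param targetRoi which bleached ROI to analyse (1 = cell center,
#'   2 = cell end).
#' @param prebleachMean passed to [normalizeFrap()].
#' @param ... passed to [fitBiexponential()].
#' @return list with `fit` (a [FRAPFit-class]), `normalized` (the
#'   normalized [FRAPTrace-class]) and `rawRecovery2minPct` (the normalized
#'   raw trace at the scan nearest 120 s after the bleach).
#' @export
analyzeFrap <- function(traces, targetRoi = 1L, prebleachMean = FALSE, ...) {
  stopifnot(all(c("roi1", "roi2", "roi3", "roi4") %in% names(traces)))
  target <- traces[[paste0("roi", targetRoi)]]
  bg <- traces$roi4
  corr <- bleachCorrect(subtractBackground(target, bg),
                        subtractBackground(traces$roi3, bg))
  norm <- normalizeFrap(corr, prebleachMean = prebleachMean)
  fit <- fitBiexponential(norm, ...)
  post <- (norm@nPrebleach + 1L):length(norm@values)
  tPost <- (seq_along(post) - 1L) * norm@scanInterval
  iRaw <- which.min(abs(tPost - 120))
  list(fit = fit, normalized = norm,
       rawRecovery2minPct = 100 * norm@values[post[iRaw]])
}

#' Read FRAP traces from a long-format table
#'
#' @param path CSV file with columns `roi`, `scan`, `value`.
#' @param scanInterval,nPrebleach acquisition metadata.
#' @return named list of [FRAPTrace-class] (`roi1`..`roi4` as present).
#' @export
readFrapTable <- function(path, scanInterval = 0.5, nPrebleach = 25L) {
  df <- utils::read.csv(path)
  stopifnot(all(c("roi", "scan", "value") %in% names(df)))
  out <- lapply(sort(unique(df$roi)), function(r) {
    sub <- df[df$roi == r, ]
    frapTrace(sub$value[order(sub$scan)], roiId = r,
              scanInterval = scanInterval, nPrebleach = nPrebleach)
  })
  names(out) <- paste0("roi", sort(unique(df$roi)))
  out
}

#' Write FRAP traces to a long-format CSV
#'
#' @param traces named list of [FRAPTrace-class].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writeFrapTable <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(roi = tr@roiId, scan = seq_along(tr@values),
               value = tr@values)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
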