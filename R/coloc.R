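# Thresholded Pearson colocalization with Costes automatic thresholds.

maskedPair <- function(a, b, mask = NULL) {
  if (!is.null(mask)) {
    m <- if (is(mask, "RegionMask")) mask@mask else mask
    if (!identical(dim(a), dim(m))) stop("mask and images must be congruent")
    list(a = a[m], b = b[m])
  } else {
    list(a = as.numeric(a), b = as.numeric(b))
  }
}

#' Pearson correlation between two channels
#'
#' Sample Pearson correlation over the masked pixels.
#'
#' @param a,b numeric matrices of identical shape.
#' @param mask optional [RegionMask-class] or logical matrix restricting the
#'   pixel set.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearsonCC <- function(a, b, mask = NULL) {
  p <- maskedPair(a, b, mask)
  if (length(p$a) < 2L) stop("need at least 2 pixels")
  if (stats::sd(p$a) == 0 || stats::sd(p$b) == 0) {
    stop("zero variance in at least one channel")
  }
  stats::cor(p$a, p$b)
}

# PCC of the below-threshold pixel population; NA when undefined (fewer than
# 2 pixels or zero variance).
pccBelow <- function(a, b, Ta, slope, intercept) {
  sel <- a < Ta & b < slope * Ta + intercept
  if (sum(sel) < 2L) return(NA_real_)
  av <- a[sel]; bv <- b[sel]
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) return(NA_real_)
  stats::cor(av, bv)
}

#' Costes automatic background thresholds
#'
#' Fits the orthogonal (total least squares) regression line `b = s a + c`
#' between the two channels, then finds by bisection the threshold `Ta` at
#' which the Pearson correlation of the pixels below the line
#' (`a < Ta` and `b < s Ta + c`) first becomes non-positive;
#' `Tb = s Ta + c`. Pixels above the thresholds are considered genuinely
#' colocalized signal, those below are background.
#'
#' @param a,b numeric matrices of identical shape.
#' @param mask optional [RegionMask-class] or logical matrix.
#' @param tol bisection tolerance in intensity units.
#' @param maxIter maximum bisection iterations.
#' @return list with `Ta`, `Tb`, `slope`, `intercept` and `undefined`
#'   (`TRUE` when the regression slope is not positive, in which case the
#'   thresholds are `NA`).
#' @export
costesThresholds <- function(a, b, mask = NULL, tol = 0.5, maxIter = 200L) {
  p <- maskedPair(a, b, mask)
  av <- p$a; bv <- p$b
  if (length(av) < 2L) stop("need at least 2 pixels")
  # orthogonal regression via the principal axis of the covariance matrix
  cv <- stats::cov(cbind(av, bv))
  ev <- eigen(cv, symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (abs(v[1]) < .Machine$double.eps) {
    return(list(Ta = NA_real_, Tb = NA_real_, slope = Inf,
                intercept = NA_real_, undefined = TRUE))
  }
  slope <- v[2] / v[1]
  intercept <- mean(bv) - slope * mean(av)
  if (slope <= 0) {
    return(list(Ta = NA_real_, Tb = NA_real_, slope = slope,
                intercept = intercept, undefined = TRUE))
  }
  lo <- min(av)   # empty below-set: treated as non-positive correlation
  hi <- max(av)
  gHi <- pccBelow(av, bv, hi, slope, intercept)
  if (!is.na(gHi) && gHi <= 0) {
    # already uncorrelated below the top: everything is background-like
    Ta <- hi
  } else {
    iter <- 0L
    while (hi - lo > tol && iter < maxIter) {
      mid <- (lo + hi) / 2
      g <- pccBelow(av, bv, mid, slope, intercept)
      if (is.na(g) || g <= 0) lo <- mid else hi <- mid
      iter <- iter + 1L
    }
    Ta <- (lo + hi) / 2
  }
  list(Ta = Ta, Tb = slope * Ta + intercept, slope = slope,
       intercept = intercept, undefined = FALSE)
}

#' Thresholded Pearson correlation coefficient
#'
#' Computes the whole-population PCC and the PCC restricted to pixels above
#' the Costes thresholds. The above-threshold pixel set convention is
#' selectable: `"either"` (default; a pixel qualifies when either channel
#' exceeds its threshold, which preserves genuine anti-correlation while
#' excluding background-dominated pixels), `"both"`, or `"all"` (no
#' thresholding).
#'
#' @inheritParams costesThresholds
#' @param pixels above-threshold pixel convention.
#' @return a `ColocResult` list: `pccAll`, `pccAboveThreshold`,
#'   `thresholdA`, `thresholdB`, `regressionSlope`, `regressionIntercept`,
#'   `nPixelsUsed`, `pixelConvention`. `pccAboveThreshold` is `NA` (with a
#'   warning) when the thresholds are undefined or fewer than 2 pixels
#'   qualify.
#' @examples
#' set.seed(1)
#' a <- matrix(runif(2500), 50); pcc <- thresholdedPCC(a, a)
#' pcc$pccAboveThreshold  # identical channels: 1
#' @export
thresholdedPCC <- function(a, b, mask = NULL,
                           pixels = c("either", "both", "all"),
                           tol = 0.5, maxIter = 200L) {
  pixels <- match.arg(pixels)
  p <- maskedPair(a, b, mask)
  pccAll <- pearsonCC(a, b, mask)
  ct <- costesThresholds(a, b, mask, tol = tol, maxIter = maxIter)
  if (ct$undefined) {
    warning("Costes thresholds undefined (non-positive regression slope)")
    pccAbove <- NA_real_
    n <- 0L
  } else {
    sel <- switch(pixels,
      either = p$a > ct$Ta | p$b > ct$Tb,
      both = p$a > ct$Ta & p$b > ct$Tb,
      all = rep(TRUE, length(p$a))
    )
    n <- sum(sel)
    if (n < 2L || stats::sd(p$a[sel]) == 0 || stats::sd(p$b[sel]) == 0) {
      warning("fewer than 2 usable above-threshold pixels")
      pccAbove <- NA_real_
    } else {
      pccAbove <- stats::cor(p$a[sel], p$b[sel])
    }
  }
  structure(list(
    pccAll = pccAll, pccAboveThreshold = pccAbove,
    thresholdA = ct$Ta, thresholdB = ct$Tb,
    regressionSlope = ct$slope, regressionIntercept = ct$intercept,
    nPixelsUsed = as.integer(n), pixelConvention = pixels
  ), class = "ColocResult")
}

#' @export
print.ColocResult <- function(x, ...) {
  cat(sprintf("ColocResult: PCC(all) = %.4f, PCC(above thresholds) = %s\n",
              x$pccAll,
              if (is.na(x$pccAboveThreshold)) "NA"
              else sprintf("%.4f", x$pccAboveThreshold)))
  cat(sprintf("  thresholds: Ta = %s, Tb = %s (%d px, '%s' convention)\n",
              format(x$thresholdA, digits = 4),
              format(x$thresholdB, digits = 4),
              x$nPixelsUsed, x$pixelConvention))
  invisible(x)
}
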