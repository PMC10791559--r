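# Generics, accessors and show methods for the core classes.

#' @rdname ImageStack-class
#' @param object,x an object
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname ImageStack-class
#' @export
setMethod("voxels", "ImageStack", function(x) x@voxels)

#' @rdname ImageStack-class
#' @export
setGeneric("pixelSizeXY", function(x) standardGeneric("pixelSizeXY"))
#' @rdname ImageStack-class
#' @export
setMethod("pixelSizeXY", "ImageStack", function(x) x@pixelXY)

#' @rdname ImageStack-class
#' @export
setGeneric("zStepUm", function(x) standardGeneric("zStepUm"))
#' @rdname ImageStack-class
#' @export
setMethod("zStepUm", "ImageStack", function(x) x@zStep)

#' @rdname ImageStack-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname ImageStack-class
#' @export
setMethod("channelNames", "ImageStack", function(x) x@channelNames)

#' Extract one channel of a stack as a 3-D array
#'
#' @param x an [ImageStack-class].
#' @param channel channel name or index.
#' @return numeric array `(ny, nx, nz)`.
#' @export
setGeneric("getChannel", function(x, channel) standardGeneric("getChannel"))
#' @rdname getChannel
#' @export
setMethod("getChannel", "ImageStack", function(x, channel) {
  ci <- resolveChannel(x, channel)
  x@voxels[, , , ci, drop = FALSE][, , , 1L]
})

resolveChannel <- function(stack, channel) {
  if (is.character(channel)) {
    ci <- match(channel, stack@channelNames)
    if (is.na(ci)) {
      stop("unknown channel '", channel, "'; available: ",
           paste(stack@channelNames, collapse = ", "))
    }
  } else {
    ci <- as.integer(channel)
    if (ci < 1L || ci > dim(stack@voxels)[4]) stop("channel index out of range")
  }
  ci
}

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@voxels)
  cat("ImageStack:", d[2], "x", d[1], "px,", d[3], "z-planes,",
      d[4], "channel(s)\n")
  cat("  pixel:", object@pixelXY * 1000, "nm XY /", object@zStep * 1000,
      "nm Z\n")
  cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
})

#' @rdname RegionMask-class
#' @param x a [RegionMask-class]
#' @export
setGeneric("maskArea", function(x) standardGeneric("maskArea"))
#' @rdname RegionMask-class
#' @export
setMethod("maskArea", "RegionMask", function(x) {
  sum(x@mask) * prod(x@pixelDims)
})

#' @rdname RegionMask-class
#' @export
setGeneric("maskValues", function(x) standardGeneric("maskValues"))
#' @rdname RegionMask-class
#' @export
setMethod("maskValues", "RegionMask", function(x) x@mask)

setMethod("show", "RegionMask", function(object) {
  cat("RegionMask:", paste(dim(object@mask), collapse = " x "), "px,",
      sum(object@mask), "set,",
      format(maskArea(object), digits = 4),
      if (length(dim(object@mask)) == 2L) "um^2\n" else "um^3\n")
})

#' @rdname ClusterSet-class
#' @param x a [ClusterSet-class]
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))
#' @rdname ClusterSet-class
#' @export
setMethod("labelMap", "ClusterSet", function(x) x@labelMap)

#' @rdname ClusterSet-class
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))
#' @rdname ClusterSet-class
#' @export
setMethod("clusterTable", "ClusterSet", function(x) x@table)

#' @rdname ClusterSet-class
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))
#' @rdname ClusterSet-class
#' @export
setMethod("nClusters", "ClusterSet", function(x) nrow(x@table))

setMethod("show", "ClusterSet", function(object) {
  cat("ClusterSet:", nrow(object@table), "cluster(s) in a",
      format(maskArea(object@roi), digits = 4), "um^2 ROI\n")
  cat("  threshold:", format(object@threshold, digits = 4),
      sprintf("(%s)\n", object@method))
})

#' @rdname FRAPTrace-class
#' @param x a [FRAPTrace-class]
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))
#' @rdname FRAPTrace-class
#' @export
setMethod("traceValues", "FRAPTrace", function(x) x@values)

#' Time axis of a FRAP trace, zeroed at the first post-bleach scan
#'
#' @param x a [FRAPTrace-class].
#' @return numeric vector of times in seconds (negative during the baseline).
#' @export
traceTimes <- function(x) {
  stopifnot(is(x, "FRAPTrace"))
  (seq_along(x@values) - (x@nPrebleach + 1L)) * x@scanInterval
}

setMethod("show", "FRAPTrace", function(object) {
  cat("FRAPTrace: ROI", object@roiId, "-", length(object@values), "scans @",
      object@scanInterval, "s,", object@nPrebleach, "pre-bleach\n")
})

#' @rdname FRAPFit-class
#' @param x a [FRAPFit-class]
#' @export
setGeneric("recovery2min", function(x) standardGeneric("recovery2min"))
#' @rdname FRAPFit-class
#' @export
setMethod("recovery2min", "FRAPFit", function(x) x@recovery2min)

#' @rdname FRAPFit-class
#' @export
setGeneric("mobileFraction", function(x) standardGeneric("mobileFraction"))
#' @rdname FRAPFit-class
#' @export
setMethod("mobileFraction", "FRAPFit", function(x) x@A1 + x@A2)

#' Evaluate a fitted FRAP recovery curve
#'
#' @param fit a [FRAPFit-class].
#' @param t times in seconds since the bleach.
#' @return fitted normalized fluorescence at `t`.
#' @export
predictRecovery <- function(fit, t) {
  stopifnot(is(fit, "FRAPFit"))
  fit@A1 * (1 - exp(-t / fit@tau1)) + fit@A2 * (1 - exp(-t / fit@tau2))
}

#' @rdname FRAPFit-class
#' @export
coefficients.FRAPFit <- function(object, ...) {
  c(A1 = object@A1, A2 = object@A2, tau1 = object@tau1, tau2 = object@tau2)
}

setMethod("show", "FRAPFit", function(object) {
  cat(sprintf(
    "FRAPFit: A1=%.4f (tau1=%.3g s), A2=%.4f (tau2=%.3g s)\n",
    object@A1, object@tau1, object@A2, object@tau2))
  cat(sprintf("  mobile fraction %.3f, recovery at 2 min %.1f%%, rss %.3g\n",
              object@A1 + object@A2, object@recovery2min, object@rss))
})

#' @rdname SweepFamily-class
#' @param x a [SweepFamily-class]
#' @export
setGeneric("sweepCurrents", function(x) standardGeneric("sweepCurrents"))
#' @rdname SweepFamily-class
#' @export
setMethod("sweepCurrents", "SweepFamily", function(x) x@current)

#' @rdname SweepFamily-class
#' @export
setGeneric("testVoltages", function(x) standardGeneric("testVoltages"))
#' @rdname SweepFamily-class
#' @export
setMethod("testVoltages", "SweepFamily", function(x) x@voltages)

setMethod("show", "SweepFamily", function(object) {
  d <- dim(object@current)
  cat("SweepFamily:", d[3], "repeat(s) x", d[2], "voltages x", d[1],
      "samples @", object@timeStepMs, "ms\n")
  cat("  ladder:", min(object@voltages), "to", max(object@voltages), "mV\n")
})
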