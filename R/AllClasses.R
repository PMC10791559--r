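#' @import methods
NULL

#' Multi-channel 3-D image stack with physical pixel sizes
#'
#' Container for a fluorescence z-stack. Voxels are stored as a numeric array
#' with dimensions `(y, x, z, channel)`; the in-plane pixel pitch and the
#' z-step are carried in micrometres so that all downstream statistics can be
#' reported in physical units.
#'
#' @slot voxels numeric array, dim `(ny, nx, nz, nchannel)`, finite and >= 0.
#' @slot pixelXY in-plane pixel pitch in micrometres (x and y share the pitch).
#' @slot zStep z-plane spacing in micrometres.
#' @slot channelNames character vector, one name per channel.
#'
#' @seealso [imageStack()], [getChannel()], [zprojectMax()], [resliceYZ()]
#' @export
setClass("ImageStack",
  representation(
    voxels = "array",
    pixelXY = "numeric",
    zStep = "numeric",
    channelNames = "character"
  )
)

setValidity("ImageStack", function(object) {
  d <- dim(object@voxels)
  if (length(d) != 4L) {
    return("voxels must be a 4-D array (y, x, z, channel)")
  }
  if (d[4] < 1L) return("at least one channel is required")
  if (length(object@channelNames) != d[4]) {
    return("channelNames length must equal the number of channels")
  }
  if (anyDuplicated(object@channelNames)) {
    return("channelNames must be unique")
  }
  if (length(object@pixelXY) != 1L || !is.finite(object@pixelXY) ||
      object@pixelXY <= 0) {
    return("pixelXY must be a single positive number (um)")
  }
  if (length(object@zStep) != 1L || !is.finite(object@zStep) ||
      object@zStep <= 0) {
    return("zStep must be a single positive number (um)")
  }
  if (!all(is.finite(object@voxels))) return("voxel intensities must be finite")
  TRUE
})

#' Boolean region mask on a pixel grid
#'
#' A 2-D (plane) or 3-D (stack) logical mask together with the physical pixel
#' dimensions of the grid it lives on, so that areas are always
#' `count * pixel area` in square micrometres. 2-D masks on YZ reslices carry
#' anisotropic pixel dimensions `(pixelXY, zStep)`.
#'
#' @slot mask logical matrix `(ny, nx)` or array `(ny, nx, nz)`.
#' @slot pixelDims physical size of one pixel along each in-plane axis, um;
#'   length 2 for planes (`(dy, dx)`), length 3 for volumes (`(dy, dx, dz)`).
#'
#' @seealso [regionMask()], [maskArea()], [rimMask()], [maskFromContour()]
#' @export
setClass("RegionMask",
  representation(mask = "array", pixelDims = "numeric")
)

setValidity("RegionMask", function(object) {
  nd <- length(dim(object@mask))
  if (!nd %in% c(2L, 3L)) return("mask must be 2-D or 3-D")
  if (!is.logical(object@mask)) return("mask must be logical")
  if (length(object@pixelDims) != nd) {
    return("pixelDims length must match mask dimensionality")
  }
  if (!all(is.finite(object@pixelDims)) || any(object@pixelDims <= 0)) {
    return("pixelDims must be positive and finite (um)")
  }
  TRUE
})

#' Labeled cluster field within a region of interest
#'
#' Result of segmenting immunofluorescence clusters inside an ROI: an integer
#' label map (0 = background, labels contiguous 1..n), the ROI, the threshold
#' that was applied (recorded for reproducibility) and a per-cluster table.
#'
#' @slot labelMap integer matrix, same shape as the ROI plane.
#' @slot roi the [RegionMask-class] the segmentation was restricted to.
#' @slot table `data.frame` with one row per cluster: `id`, `areaUm2`,
#'   `meanIntensity` (raw mean over cluster pixels).
#' @slot threshold numeric, the applied intensity threshold.
#' @slot method character, the threshold rule that produced it.
#'
#' @seealso [segmentClusters()], [clusterStats()]
#' @export
setClass("ClusterSet",
  representation(
    labelMap = "matrix",
    roi = "RegionMask",
    table = "data.frame",
    threshold = "numeric",
    method = "character"
  )
)

setValidity("ClusterSet", function(object) {
  if (!identical(dim(object@labelMap), dim(object@roi@mask))) {
    return("labelMap and roi must have the same shape")
  }
  labs <- sort(unique(object@labelMap[object@labelMap > 0]))
  if (length(labs) && !identical(as.integer(labs), seq_along(labs))) {
    return("labels must be contiguous 1..n")
  }
  if (length(labs) != nrow(object@table)) {
    return("cluster table must have one row per label")
  }
  if (any(object@labelMap > 0 & !object@roi@mask)) {
    return("every labeled pixel must lie inside the roi")
  }
  TRUE
})

#' Single-ROI FRAP intensity time series
#'
#' Mean fluorescence intensity of one ROI per scan, at a fixed scan interval.
#' ROI ids follow the acquisition convention: 1 = cell center (bleached),
#' 2 = cell end (bleached), 3 = unbleached in-cell reference, 4 = cell-free
#' background.
#'
#' @slot values numeric vector, one intensity per scan.
#' @slot roiId integer 1..4.
#' @slot scanInterval seconds between scans (default acquisition 0.5 s).
#' @slot nPrebleach number of baseline scans before the bleach pulse.
#'
#' @seealso [frapTrace()], [bleachCorrect()], [normalizeFrap()]
#' @export
setClass("FRAPTrace",
  representation(
    values = "numeric",
    roiId = "integer",
    scanInterval = "numeric",
    nPrebleach = "integer"
  )
)

setValidity("FRAPTrace", function(object) {
  if (!all(is.finite(object@values))) return("trace values must be finite")
  if (!object@roiId %in% 1:4) return("roiId must be 1, 2, 3 or 4")
  if (object@scanInterval <= 0) return("scanInterval must be positive")
  if (object@nPrebleach < 1L || object@nPrebleach >= length(object@values)) {
    return("nPrebleach must leave at least one post-bleach scan")
  }
  TRUE
})

#' Constrained biexponential FRAP recovery fit
#'
#' Parameters of the saturating two-exponential recovery
#' `N(t) = A1 (1 - exp(-t/tau1)) + A2 (1 - exp(-t/tau2))` fitted to a
#' normalized post-bleach trace, with `tau1 < tau2`. The fitted curve is
#' anchored at `N(0) = 0`; the plateau `A1 + A2` is the mobile fraction.
#'
#' @slot A1,A2 non-negative fractional amplitudes.
#' @slot tau1,tau2 time constants in seconds, `tau1 < tau2`.
#' @slot rss residual sum of squares of the winning fit.
#' @slot recovery2min fitted fractional recovery at 120 s, in percent.
#'
#' @seealso [fitBiexponential()], [recovery2min()], [mobileFraction()]
#' @export
setClass("FRAPFit",
  representation(
    A1 = "numeric", A2 = "numeric",
    tau1 = "numeric", tau2 = "numeric",
    rss = "numeric", recovery2min = "numeric"
  )
)

setValidity("FRAPFit", function(object) {
  if (object@A1 < 0 || object@A2 < 0) return("amplitudes must be >= 0")
  if (object@tau1 > object@tau2) return("time constants must satisfy tau1 <= tau2")
  TRUE
})

#' Family of voltage-clamp current sweeps
#'
#' Repeated current families from one membrane patch: a `(time, voltage,
#' repeat)` array of currents in pA (inward negative), the test-voltage ladder
#' in mV, the sampling interval and the index window of the test pulse.
#'
#' @slot current numeric array, dim `(nTime, nVoltage, nRepeat)`.
#' @slot timeStepMs sampling interval in ms.
#' @slot voltages test-voltage ladder in mV, strictly monotone.
#' @slot pulseStart index of the first sample of the test pulse.
#'
#' @seealso [sweepFamily()], [ensembleAverage()], [peakIna()]
#' @export
setClass("SweepFamily",
  representation(
    current = "array",
    timeStepMs = "numeric",
    voltages = "numeric",
    pulseStart = "integer"
  )
)

setValidity("SweepFamily", function(object) {
  d <- dim(object@current)
  if (length(d) != 3L) return("current must be (time, voltage, repeat)")
  if (d[3] < 1L) return("at least one repeat is required")
  if (length(object@voltages) != d[2]) {
    return("voltage ladder length must match the current array")
  }
  dv <- diff(object@voltages)
  if (length(dv) && !(all(dv > 0) || all(dv < 0))) {
    return("voltage ladder must be strictly monotone")
  }
  if (object@timeStepMs <= 0) return("timeStepMs must be positive")
  if (object@pulseStart < 1L || object@pulseStart > d[1]) {
    return("pulseStart out of range")
  }
  TRUE
})
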