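# Cluster segmentation and the three cluster parameters
# (density %, average size um^2, mean intensity in clusters).

#' Segment immunofluorescence clusters inside an ROI
#'
#' Signals outside the ROI are cleared, pixels at or above the threshold
#' become foreground, and 8-connected components of at least `minSizePx`
#' pixels become clusters. The applied threshold and rule are recorded in
#' the result so every segmentation is reproducible.
#'
#' @param image numeric matrix (one plane).
#' @param roi a non-empty [RegionMask-class] congruent with `image`.
#' @param thresholdMethod `"otsu"` (computed within the ROI, the default),
#'   `"mean_sd"` (ROI mean + `k` s.d.) or `"fixed"`.
#' @param k multiplier for `"mean_sd"`.
#' @param fixedThreshold threshold value for `"fixed"`.
#' @param minSizePx minimum cluster size in pixels (default 4 suppresses
#'   single-pixel noise).
#' @return a [ClusterSet-class]. An all-foreground or all-background result
#'   under the chosen rule produces a warning, not an error.
#' @examples
#' img <- matrix(0, 100, 100); img[40:47, 40:47] <- 10
#' roi <- regionMask(matrix(TRUE, 100, 100), 0.05)
#' cs <- segmentClusters(img, roi, thresholdMethod = "fixed",
#'                       fixedThreshold = 5)
#' clusterStats(cs)
#' @export
segmentClusters <- function(image, roi,
                            thresholdMethod = c("otsu", "mean_sd", "fixed"),
                            k = 2, fixedThreshold = NULL, minSizePx = 4L) {
  thresholdMethod <- match.arg(thresholdMethod)
  stopifnot(is(roi, "RegionMask"))
  if (!identical(dim(image), dim(roi@mask))) {
    stop("image and roi must be congruent")
  }
  if (!any(roi@mask)) stop("roi is empty")
  vals <- image[roi@mask]
  if (thresholdMethod != "fixed" && diff(range(vals)) == 0) {
    # contrast-free ROI: no signal to segment
    thr <- Inf
  } else {
  thr <- switch(thresholdMethod,
    otsu = otsuThreshold(vals),
    mean_sd = mean(vals) + k * stats::sd(vals),
    fixed = {
      if (is.null(fixedThreshold)) stop("fixedThreshold is required")
      fixedThreshold
    }
  )
  }
  cleared <- image
  cleared[!roi@mask] <- 0
  fg <- roi@mask & (image >= thr)
  if (all(fg[roi@mask])) {
    warning("threshold selects the entire ROI as foreground")
  } else if (!any(fg)) {
    warning("threshold selects no foreground pixels")
  }
  lab <- label8(fg)
  pxArea <- prod(roi@pixelDims)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= minSizePx)
    relab <- integer(length(sizes))
    relab[keep] <- seq_along(keep)
    lab[lab > 0L] <- relab[lab[lab > 0L]]
  }
  n <- max(lab)
  if (n > 0L) {
    px <- tabulate(lab[lab > 0L], nbins = n)
    sums <- vapply(seq_len(n), function(i) sum(image[lab == i]), numeric(1))
    tab <- data.frame(id = seq_len(n), areaUm2 = px * pxArea,
                      meanIntensity = sums / px)
  } else {
    tab <- data.frame(id = integer(0), areaUm2 = numeric(0),
                      meanIntensity = numeric(0))
  }
  new("ClusterSet", labelMap = lab, roi = roi, table = tab,
      threshold = as.numeric(thr), method = thresholdMethod)
}

#' Cluster parameters of a segmented field
#'
#' Computes the three cluster parameters: density (% of the ROI area occupied
#' by clusters), average cluster size (um^2) and mean immunofluorescence
#' intensity over cluster pixels (background-subtracted; the raw mean is also
#' reported). Mean fields are `NA` when there are no clusters.
#'
#' @param cs a [ClusterSet-class].
#' @param background background intensity subtracted from the cluster mean,
#'   `>= 0`.
#' @return one-row `data.frame`: `nClusters`, `densityPct`, `meanSizeUm2`,
#'   `meanIntensity`, `rawMeanIntensity`.
#' @export
clusterStats <- function(cs, background = 0) {
  stopifnot(is(cs, "ClusterSet"))
  if (background < 0) stop("background must be >= 0")
  tab <- cs@table
  roiArea <- maskArea(cs@roi)
  if (nrow(tab) == 0L) {
    return(data.frame(nClusters = 0L, densityPct = 0, meanSizeUm2 = NA_real_,
                      meanIntensity = NA_real_, rawMeanIntensity = NA_real_))
  }
  pxArea <- prod(cs@roi@pixelDims)
  px <- tab$areaUm2 / pxArea
  pooledMean <- sum(tab$meanIntensity * px) / sum(px)
  data.frame(
    nClusters = nrow(tab),
    densityPct = 100 * sum(tab$areaUm2) / roiArea,
    meanSizeUm2 = mean(tab$areaUm2),
    meanIntensity = pooledMean - background,
    rawMeanIntensity = pooledMean
  )
}

#' En-face intercalated-disc cluster profile
#'
#' For each requested x position near the cell end: reslice the stack into a
#' YZ plane, segment the ICD-marker channel (threshold, fill holes, keep
#' components of at least `icdMinAreaUm2`) to define the ICD ROI, then
#' segment the target channel inside that ROI and report its cluster
#' parameters. A position without ICD-marker signal yields a missing row,
#' not an error.
#'
#' @param stack an [ImageStack-class].
#' @param ncadChannel,targetChannel channel names of the ICD marker and the
#'   protein of interest.
#' @param xPositionsUm x positions of the reslices, um.
#' @param icdMinAreaUm2 minimum component area accepted as ICD, um^2.
#' @param background background level subtracted from cluster intensities.
#' @param ... further arguments to [segmentClusters()] for the target
#'   channel.
#' @return `data.frame`, one row per position: `xUm`, `icdAreaUm2`,
#'   cluster parameters (`NA` where missing).
#' @export
icdClusterProfile <- function(stack, ncadChannel = "ncad",
                              targetChannel = "target", xPositionsUm,
                              icdMinAreaUm2 = 0.5, background = 0, ...) {
  if (!length(xPositionsUm)) stop("at least one x position is required")
  ncadPl <- resliceYZ(stack, ncadChannel, xPositionsUm)
  targPl <- resliceYZ(stack, targetChannel, xPositionsUm)
  pxDims <- c(stack@pixelXY, stack@zStep)
  pxArea <- prod(pxDims)
  # one systemic marker threshold for the whole stack, so that planes
  # without genuine ICD signal yield no ROI instead of a spurious one
  thr <- otsuThreshold(as.numeric(getChannel(stack, ncadChannel)))
  empty <- data.frame(nClusters = NA_integer_, densityPct = NA_real_,
                      meanSizeUm2 = NA_real_, meanIntensity = NA_real_,
                      rawMeanIntensity = NA_real_)
  rows <- lapply(seq_along(xPositionsUm), function(i) {
    npl <- ncadPl[[i]]
    fgN <- npl >= thr
    if (!any(fgN)) {
      return(cbind(data.frame(xUm = xPositionsUm[i], icdAreaUm2 = NA_real_),
                   empty))
    }
    filled <- EBImage::fillHull(fgN) > 0
    lab <- label8(filled)
    keep <- which(tabulate(lab[lab > 0L]) * pxArea >= icdMinAreaUm2)
    roiM <- matrix(lab %in% keep & lab > 0L, nrow(npl), ncol(npl))
    if (!any(roiM)) {
      return(cbind(data.frame(xUm = xPositionsUm[i], icdAreaUm2 = NA_real_),
                   empty))
    }
    roi <- regionMask(roiM, pxDims)
    cs <- segmentClusters(targPl[[i]], roi, ...)
    cbind(data.frame(xUm = xPositionsUm[i], icdAreaUm2 = maskArea(roi)),
          clusterStats(cs, background = background))
  })
  do.call(rbind, rows)
}

#' Percent of a region occupied by segmented puncta
#'
#' Occupancy statistic used for e.g. microtubule density: segment within the
#' region and return the density percentage only.
#'
#' @inheritParams segmentClusters
#' @param region the [RegionMask-class] to analyse within.
#' @param ... further arguments to [segmentClusters()].
#' @return density, % of region area occupied.
#' @export
occupancyPct <- function(image, region, ...) {
  cs <- segmentClusters(image, region, ...)
  clusterStats(cs)$densityPct
}
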