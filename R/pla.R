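# Proximity ligation assay puncta density and expression correction.

#' PLA puncta density of a cell
#'
#' Collapses the PLA channel by maximum-intensity z-projection, segments
#' puncta within the cell mask and returns the percentage of cellular area
#' occupied by PLA puncta together with the punctum count.
#'
#' For comparability across experimental groups the threshold should be one
#' fixed rule per batch -- either `thresholdMethod = "fixed"` with a value
#' from [pooledOtsuThreshold()], or the same method applied uniformly --
#' never tuned per image.
#'
#' @param stack an [ImageStack-class].
#' @param plaChannel channel name or index of the PLA signal.
#' @param cell non-empty cell [RegionMask-class] (from the cellular
#'   contour).
#' @param minSizePx minimum punctum size in pixels (default 2).
#' @param ... further arguments to [segmentClusters()]
#'   (`thresholdMethod`, `fixedThreshold`, ...).
#' @return list with `densityPct`, `nPuncta` and the underlying
#'   [ClusterSet-class] (`clusters`).
#' @export
plaDensity <- function(stack, plaChannel, cell, minSizePx = 2L, ...) {
  stopifnot(is(cell, "RegionMask"))
  if (!any(cell@mask)) stop("cell mask is empty")
  proj <- zprojectMax(stack, plaChannel)
  cs <- segmentClusters(proj, cell, minSizePx = minSizePx, ...)
  st <- clusterStats(cs)
  list(densityPct = st$densityPct, nPuncta = st$nClusters, clusters = cs)
}

#' Otsu threshold over a pooled batch histogram
#'
#' One threshold for a whole batch of images: Otsu computed on the pooled
#' in-mask pixel values of all images, implementing the "segmented in a
#' systemic manner" requirement across comparison groups.
#'
#' @param images list of numeric matrices.
#' @param masks list of [RegionMask-class] (or logical matrices), parallel
#'   to `images`; `NULL` pools whole images.
#' @return threshold value.
#' @export
pooledOtsuThreshold <- function(images, masks = NULL) {
  vals <- unlist(lapply(seq_along(images), function(i) {
    if (is.null(masks)) as.numeric(images[[i]])
    else {
      m <- masks[[i]]
      images[[i]][if (is(m, "RegionMask")) m@mask else m]
    }
  }))
  otsuThreshold(vals)
}

#' Expression-corrected PLA density
#'
#' Divides a cell's PLA puncta density by the product of its normalized
#' expression pixel contents: `density / ((pc1/mean1) * (pc2/mean2))`, where
#' the means are the group (batch) means of the two expression channels.
#' This removes trivial density increases caused by higher expression of
#' either interaction partner.
#'
#' @param densityPct raw PLA puncta density, %.
#' @param pc1,pc2 this cell's pixel contents of the two expression channels.
#' @param groupMeanPc1,groupMeanPc2 batch mean pixel contents (must be
#'   positive).
#' @return corrected density, or `NA` (with a warning) if either pixel
#'   content is non-positive.
#' @export
correctedPlaDensity <- function(densityPct, pc1, pc2,
                                groupMeanPc1, groupMeanPc2) {
  if (groupMeanPc1 <= 0 || groupMeanPc2 <= 0) {
    stop("group mean pixel contents must be positive")
  }
  if (pc1 <= 0 || pc2 <= 0) {
    warning("non-positive expression pixel content; corrected density is NA")
    return(NA_real_)
  }
  densityPct / ((pc1 / groupMeanPc1) * (pc2 / groupMeanPc2))
}
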