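# Pixel contents and degrees of enrichment (lateral rim, intercalated disc).

#' Pixel content of a region
#'
#' Pixel content = background-subtracted mean pixel value times region area
#' (intensity x um^2), the expression surrogate used throughout the
#' quantification.
#'
#' @param image numeric matrix (the analysis plane).
#' @param mask non-empty [RegionMask-class] congruent with `image`.
#' @param background background intensity, `>= 0`.
#' @return pixel content (scalar; can be negative if the region is dimmer
#'   than the background -- negatives are preserved here and only clipped in
#'   percentage reporting).
#' @export
pixelContent <- function(image, mask, background = 0) {
  stopifnot(is(mask, "RegionMask"))
  if (!any(mask@mask)) stop("mask is empty")
  if (background < 0) stop("background must be >= 0")
  if (!identical(dim(image), dim(mask@mask))) {
    stop("image and mask must be congruent")
  }
  (mean(image[mask@mask]) - background) * maskArea(mask)
}

enrichmentResult <- function(image, cell, region, background, regionKind) {
  pcCell <- pixelContent(image, cell, background)
  if (pcCell <= 0) {
    stop("cellular pixel content is not positive: ",
         "image indistinguishable from background")
  }
  pcRegion <- pixelContent(image, region, background)
  pctPC <- 100 * pcRegion / pcCell
  pctArea <- 100 * maskArea(region) / maskArea(cell)
  structure(list(
    pixelContentTotal = pcCell,
    pixelContentRegion = pcRegion,
    pctPixelContentRegion = max(0, pctPC),
    pctAreaRegion = pctArea,
    enrichment = pctPC / pctArea,
    regionKind = regionKind,
    background = background
  ), class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf(
    "EnrichmentResult (%s): %.2f%% of pixel content in %.2f%% of area -> enrichment %.4g\n",
    x$regionKind, x$pctPixelContentRegion, x$pctAreaRegion, x$enrichment))
  invisible(x)
}

#' Degree of enrichment on the lateral surface
#'
#' The percent of cellular pixel content falling inside the membrane rim
#' divided by the percent of cellular area the rim occupies; 1 means a
#' uniform distribution, larger values mean enrichment along the lateral
#' surface.
#'
#' @param image numeric matrix (single analysis plane; conventionally the
#'   central z-plane with a clearly defined contour).
#' @param cell cell [RegionMask-class].
#' @param rim rim [RegionMask-class]; must be a subset of `cell` (see
#'   [rimMask()]).
#' @param background background intensity.
#' @return an `EnrichmentResult` list: `pixelContentTotal`,
#'   `pixelContentRegion`, `pctPixelContentRegion` (clipped at 0),
#'   `pctAreaRegion`, `enrichment`, `regionKind`, `background`.
#' @export
lateralEnrichment <- function(image, cell, rim, background = 0) {
  if (any(rim@mask & !cell@mask)) stop("rim must be a subset of the cell")
  enrichmentResult(image, cell, rim, background, "lateral")
}

#' Degree of enrichment at intercalated discs
#'
#' As [lateralEnrichment()] with the ICD-marker-demarcated region. An empty
#' ICD mask yields `NA` with a warning (no discs detected), not an error.
#'
#' @inheritParams lateralEnrichment
#' @param icd ICD [RegionMask-class], subset of `cell`, typically obtained
#'   by segmenting and hole-filling the marker channel.
#' @return an `EnrichmentResult`, or `NA` if the ICD mask is empty.
#' @export
icdEnrichment <- function(image, cell, icd, background = 0) {
  if (!any(icd@mask)) {
    warning("empty ICD mask: no intercalated disc detected")
    return(NA)
  }
  if (any(icd@mask & !cell@mask)) stop("icd must be a subset of the cell")
  enrichmentResult(image, cell, icd, background, "icd")
}

#' Pick the analysis plane with the largest cell cross-section
#'
#' Helper implementing the "central z-plane with a clearly defined cellular
#' contour" convention: returns the z index maximizing in-plane cell-mask
#' area.
#'
#' @param cellMask3d logical array `(ny, nx, nz)` of the cell volume.
#' @return z index of the default analysis plane.
#' @export
selectCentralPlane <- function(cellMask3d) {
  stopifnot(length(dim(cellMask3d)) == 3L)
  which.max(apply(cellMask3d, 3, sum))
}
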