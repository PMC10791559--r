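# Synthetic myocyte image phantom with exact ground truth.

#' Specification of a synthetic myocyte image phantom
#'
#' Collects the geometric, optical and noise parameters of the image
#' generator. The cell is a stadium-shaped (rounded-end) footprint of
#' `cellLengthUm x cellWidthUm` extruded over `cellHeightUm` of z, embedded
#' in a frame with `frameMarginUm` of cell-free margin on every side. The
#' interior carries a sarcomeric striation pattern (~2 um period); a lateral
#' rim of `rimWidthUm` and transverse intercalated-disc (ICD) bands of
#' `icdDepthUm` at both cell ends are intensity-weighted so that the measured
#' degrees of enrichment equal `lateralEnrichment` / `icdEnrichment` exactly
#' in the noiseless image. Surface clusters are disks planted on the top
#' cell z-plane. Optics are an anisotropic Gaussian PSF (FWHM 100 nm lateral
#' / 300 nm axial at the default whole-cell geometry); noise is
#' Poisson-Gaussian: `Poisson(photonScale * signal) / photonScale +
#' N(0, readNoiseSd)`.
#'
#' @param cellLengthUm,cellWidthUm,cellHeightUm cell dimensions, um. The
#'   defaults are conventional for adult rat ventricular myocytes.
#' @param frameLengthUm,frameWidthUm optional frame size, um; defaults to the
#'   cell plus `2 * frameMarginUm`. A frame smaller than the cell is an error.
#' @param frameMarginUm cell-free margin around the cell, um.
#' @param striationPeriodUm sarcomeric striation period, um (~2 um).
#' @param striationAmp relative amplitude of the striation pattern.
#' @param rimWidthUm lateral-surface rim width, um.
#' @param lateralEnrichment,icdEnrichment target degrees of enrichment
#'   (1 = uniform) on the rim and at ICDs; must be >= 0 and geometrically
#'   attainable (enrichment x region area fraction < 1).
#' @param icdDepthUm depth of the transverse ICD band at each cell end, um.
#' @param clusterDensityPct percent of the surface ROI covered by planted
#'   clusters, in `[0, 100]`.
#' @param clusterRadiusUm,clusterIntensity cluster disk radius (um) and added
#'   intensity.
#' @param background constant background intensity outside and inside the
#'   cell.
#' @param psfFwhmXYNm,psfFwhmZNm PSF full width at half maximum, nm.
#' @param pixelXYNm,zStepNm voxel pitch, nm (whole-cell mode 100/300,
#'   cluster mode 50/50).
#' @param photonScale photons per intensity unit for the Poisson noise
#'   component; higher = cleaner.
#' @param readNoiseSd standard deviation of the additive Gaussian read noise.
#' @param applyPsf,applyNoise switches for the optical blur and the noise
#'   model (off = ground-truth imaging).
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return a `PhantomSpec` (validated list).
#' @seealso [makeMyocyteStack()]
#' @export
phantomSpec <- function(cellLengthUm = 120, cellWidthUm = 25,
                        cellHeightUm = 12,
                        frameLengthUm = NULL, frameWidthUm = NULL,
                        frameMarginUm = 2,
                        striationPeriodUm = 2, striationAmp = 0.5,
                        rimWidthUm = 1,
                        lateralEnrichment = 1, icdEnrichment = 1,
                        icdDepthUm = 1,
                        clusterDensityPct = 0, clusterRadiusUm = 0.25,
                        clusterIntensity = 4,
                        background = 0.1,
                        psfFwhmXYNm = 100, psfFwhmZNm = 300,
                        pixelXYNm = 100, zStepNm = 300,
                        photonScale = 100, readNoiseSd = 0.02,
                        applyPsf = TRUE, applyNoise = TRUE,
                        seed = 1L) {
  spec <- list(
    cellLengthUm = cellLengthUm, cellWidthUm = cellWidthUm,
    cellHeightUm = cellHeightUm,
    frameLengthUm = if (is.null(frameLengthUm))
      cellLengthUm + 2 * frameMarginUm else frameLengthUm,
    frameWidthUm = if (is.null(frameWidthUm))
      cellWidthUm + 2 * frameMarginUm else frameWidthUm,
    striationPeriodUm = striationPeriodUm, striationAmp = striationAmp,
    rimWidthUm = rimWidthUm,
    lateralEnrichment = lateralEnrichment, icdEnrichment = icdEnrichment,
    icdDepthUm = icdDepthUm,
    clusterDensityPct = clusterDensityPct,
    clusterRadiusUm = clusterRadiusUm, clusterIntensity = clusterIntensity,
    background = background,
    psfFwhmXYNm = psfFwhmXYNm, psfFwhmZNm = psfFwhmZNm,
    pixelXYNm = pixelXYNm, zStepNm = zStepNm,
    photonScale = photonScale, readNoiseSd = readNoiseSd,
    applyPsf = isTRUE(applyPsf), applyNoise = isTRUE(applyNoise),
    seed = as.integer(seed)
  )
  geom <- c("cellLengthUm", "cellWidthUm", "cellHeightUm", "frameLengthUm",
            "frameWidthUm", "striationPeriodUm", "rimWidthUm", "icdDepthUm",
            "clusterRadiusUm", "pixelXYNm", "zStepNm", "psfFwhmXYNm",
            "psfFwhmZNm")
  for (f in geom) {
    if (!is.finite(spec[[f]]) || spec[[f]] <= 0) {
      stop(f, " must be strictly positive")
    }
  }
  if (spec$clusterDensityPct < 0 || spec$clusterDensityPct > 100) {
    stop("clusterDensityPct must be in [0, 100]")
  }
  if (spec$lateralEnrichment < 0 || spec$icdEnrichment < 0) {
    stop("enrichment factors must be >= 0")
  }
  if (spec$background < 0) stop("background must be >= 0")
  if (spec$photonScale <= 0) stop("photonScale must be strictly positive")
  if (spec$readNoiseSd < 0) stop("readNoiseSd must be >= 0")
  if (spec$clusterIntensity <= 0) stop("clusterIntensity must be > 0")
  if (spec$frameLengthUm < cellLengthUm + 2 * spec$pixelXYNm / 1000 ||
      spec$frameWidthUm < cellWidthUm + 2 * spec$pixelXYNm / 1000) {
    stop("cell does not fit inside the requested frame")
  }
  if (cellLengthUm <= cellWidthUm) {
    stop("cellLengthUm must exceed cellWidthUm (elongated myocyte)")
  }
  structure(spec, class = "PhantomSpec")
}

# Stadium-shaped footprint: pixels within cellWidth/2 of the midline segment.
stadiumMask <- function(spec, nx, ny, px) {
  x0 <- (spec$frameLengthUm - spec$cellLengthUm) / 2
  y0 <- (spec$frameWidthUm - spec$cellWidthUm) / 2
  hw <- spec$cellWidthUm / 2
  yc <- y0 + hw
  ax <- x0 + hw
  bx <- x0 + spec$cellLengthUm - hw
  cx <- (seq_len(nx) - 0.5) * px
  cy <- (seq_len(ny) - 0.5) * px
  X <- matrix(rep(cx, each = ny), ny, nx)
  Y <- matrix(rep(cy, times = nx), ny, nx)
  Xc <- pmin(pmax(X, ax), bx)
  inside <- (X - Xc)^2 + (Y - yc)^2 <= hw^2
  list(mask = inside, x0 = x0, X = X, Y = Y)
}

# Place non-overlapping cluster disks inside a footprint; returns the disk
# pixel mask and the cluster table. Deterministic under the active RNG state.
placeClusters <- function(roiMask, spec, px) {
  ny <- nrow(roiMask); nx <- ncol(roiMask)
  rpx <- spec$clusterRadiusUm / px
  off <- expand.grid(dy = -ceiling(rpx):ceiling(rpx),
                     dx = -ceiling(rpx):ceiling(rpx))
  off <- off[sqrt(off$dy^2 + off$dx^2) <= rpx, , drop = FALSE]
  diskPx <- nrow(off)
  nRoi <- sum(roiMask)
  targetPx <- spec$clusterDensityPct / 100 * nRoi
  nDisks <- round(targetPx / diskPx)
  diskMask <- matrix(FALSE, ny, nx)
  tab <- data.frame(cx = numeric(0), cy = numeric(0), radiusUm = numeric(0),
                    intensity = numeric(0), areaUm2 = numeric(0))
  if (nDisks == 0L) return(list(diskMask = diskMask, table = tab))
  # admissible centers: disk fully inside the ROI
  er <- EBImage::erode(roiMask,
                       EBImage::makeBrush(2L * ceiling(rpx) + 1L, "disc"))
  cand <- which(er > 0)
  minSep <- 2 * spec$clusterRadiusUm + 3 * px
  centers <- matrix(numeric(0), 0, 2)
  attempts <- 0L
  while (nrow(centers) < nDisks && attempts < 50L * nDisks &&
         length(cand)) {
    attempts <- attempts + 1L
    k <- cand[sample.int(length(cand), 1L)]
    iy <- (k - 1L) %% ny + 1L
    ix <- (k - 1L) %/% ny + 1L
    cxy <- c((ix - 0.5) * px, (iy - 0.5) * px)
    if (nrow(centers)) {
      d2 <- (centers[, 1] - cxy[1])^2 + (centers[, 2] - cxy[2])^2
      if (min(d2) < minSep^2) next
    }
    centers <- rbind(centers, cxy)
    yy <- iy + off$dy; xx <- ix + off$dx
    diskMask[cbind(yy, xx)] <- TRUE
  }
  if (nrow(centers) < nDisks) {
    warning("placed ", nrow(centers), " of ", nDisks,
            " requested clusters (geometry too crowded)")
  }
  tab <- data.frame(
    cx = centers[, 1], cy = centers[, 2],
    radiusUm = spec$clusterRadiusUm, intensity = spec$clusterIntensity,
    areaUm2 = diskPx * px^2
  )
  list(diskMask = diskMask, table = tab)
}

# Solve the rim/ICD intensity weights so that the measured degrees of
# enrichment over the rasterized geometry equal the requested factors.
solveEnrichmentWeights <- function(u, cell, rim, icd, eL, eI) {
  P1 <- rim & !icd       # rim only
  P2 <- icd              # ICD (takes precedence where the two overlap)
  P3 <- rim & icd
  S0 <- sum(u[cell & !rim & !icd])
  S1 <- sum(u[P1])
  S2 <- sum(u[icd & !rim])
  S3 <- sum(u[P3])
  aCell <- sum(cell); aR <- sum(rim); aI <- sum(icd)
  fL <- aR / aCell; fI <- aI / aCell
  if (eL * fL >= 1) stop("lateralEnrichment too large for the rim geometry")
  if (eI * fI >= 1) stop("icdEnrichment too large for the ICD geometry")
  A <- rbind(
    c(S1 * (1 - eL * fL), S3 - eL * fL * (S2 + S3)),
    c(-eI * fI * S1, (S2 + S3) * (1 - eI * fI))
  )
  b <- c(eL * fL * S0, eI * fI * S0)
  w <- solve(A, b)
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("requested enrichment factors are not attainable with this geometry")
  }
  list(cRim = w[1], cIcd = w[2], P1 = P1, P2 = P2)
}

#' Generate a synthetic myocyte image stack with ground truth
#'
#' Builds a two-channel z-stack -- a target-protein channel (striations,
#' lateral-rim and ICD enrichment, surface clusters) and an ICD-marker
#' channel emulating nCadherin -- then applies the anisotropic Gaussian PSF
#' and Poisson-Gaussian noise as requested by the spec. The returned truth
#' record carries the exact masks, cluster table and enrichment factors of
#' the noiseless geometry for recovery testing.
#'
#' @param spec a [phantomSpec()].
#' @return list with elements `stack` (an [ImageStack-class] with channels
#'   `target` and `ncad`) and `truth` (a `PhantomTruth` list: `cellMask`,
#'   `rimMask`, `icdMask`, `bgMask`, cluster table, true enrichment factors,
#'   true cluster density/size, `surfaceZ`, `centralZ`).
#' @examples
#' ph <- makeMyocyteStack(phantomSpec(cellLengthUm = 30, cellWidthUm = 12,
#'                                    cellHeightUm = 1.5, applyPsf = FALSE,
#'                                    applyNoise = FALSE))
#' ph$stack
#' @export
makeMyocyteStack <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  px <- spec$pixelXYNm / 1000
  zs <- spec$zStepNm / 1000
  nx <- round(spec$frameLengthUm / px)
  ny <- round(spec$frameWidthUm / px)
  nzc <- max(1L, round(spec$cellHeightUm / zs))
  nz <- nzc + 2L   # one cell-free z margin on each side
  zCell <- seq_len(nzc) + 1L
  surfaceZ <- max(zCell)
  centralZ <- zCell[ceiling(nzc / 2)]

  geo <- stadiumMask(spec, nx, ny, px)
  cell <- geo$mask
  cellRM <- regionMask(cell, px)
  rim <- maskValues(rimMask(cellRM, spec$rimWidthUm))
  xRel <- geo$X - geo$x0
  icd <- cell & (xRel <= spec$icdDepthUm |
                 xRel >= spec$cellLengthUm - spec$icdDepthUm)

  # striation pattern (unit mean 1 + amp/2), zero outside the cell; a
  # single-plane phantom is a pure surface view, which carries no striations
  u <- 1 + spec$striationAmp *
    0.5 * (1 + cos(2 * pi * xRel / spec$striationPeriodUm))
  if (nzc == 1L) u[] <- 1
  u[!cell] <- 0

  w <- solveEnrichmentWeights(u, cell, rim, icd,
                              spec$lateralEnrichment, spec$icdEnrichment)
  plane <- u
  plane[w$P1] <- u[w$P1] * w$cRim
  plane[w$P2] <- u[w$P2] * w$cIcd
  # the top surface shows membrane clusters on a smooth base: striations
  # are interior sarcomeric structure and do not appear on the surface view
  surfBase <- as.numeric(cell)
  surfBase[w$P1] <- w$cRim
  surfBase[w$P2] <- w$cIcd

  res <- withSeed(spec$seed, {
    cl <- placeClusters(cell, spec, px)

    target <- array(spec$background, c(ny, nx, nz))
    for (zi in zCell) target[, , zi] <- target[, , zi] + plane
    target[, , surfaceZ] <- spec$background + surfBase +
      spec$clusterIntensity * cl$diskMask

    ncad <- array(spec$background, c(ny, nx, nz))
    for (zi in zCell) {
      ncad[, , zi] <- ncad[, , zi] + 0.2 * cell + 2 * icd
    }

    if (spec$applyPsf) {
      fx <- spec$psfFwhmXYNm / 1000
      fz <- spec$psfFwhmZNm / 1000
      target <- blurStack(target, fx, fz, px, zs)
      ncad <- blurStack(ncad, fx, fz, px, zs)
    }
    if (spec$applyNoise) {
      addNoise <- function(a) {
        n <- length(a)
        out <- stats::rpois(n, spec$photonScale * pmax(a, 0)) /
          spec$photonScale
        out <- out + stats::rnorm(n, 0, spec$readNoiseSd)
        array(out, dim(a))
      }
      target <- addNoise(target)
      ncad <- addNoise(ncad)
    }
    list(target = target, ncad = ncad, clusters = cl)
  })

  vox <- array(0, c(ny, nx, nz, 2L))
  vox[, , , 1L] <- pmax(res$target, 0)
  vox[, , , 2L] <- pmax(res$ncad, 0)
  stack <- imageStack(vox, pixelXY = px, zStep = zs,
                      channelNames = c("target", "ncad"))

  nRoi <- sum(cell)
  clPx <- sum(res$clusters$diskMask)
  truth <- structure(list(
    cellMask = cellRM,
    rimMask = regionMask(rim, px),
    icdMask = regionMask(icd, px),
    bgMask = regionMask(!cell & EBImage::distmap(!cell) * px > 0.5, px),
    clusterTable = res$clusters$table,
    trueLateralEnrichment = spec$lateralEnrichment,
    trueIcdEnrichment = spec$icdEnrichment,
    trueClusterDensityPct = 100 * clPx / nRoi,
    trueClusterMeanSizeUm2 = if (nrow(res$clusters$table))
      mean(res$clusters$table$areaUm2) else NA_real_,
    clusterMask = regionMask(res$clusters$diskMask, px),
    surfaceZ = surfaceZ, centralZ = centralZ, zCell = zCell,
    background = spec$background
  ), class = "PhantomTruth")

  list(stack = stack, truth = truth)
}

#' @export
print.PhantomTruth <- function(x, ...) {
  cat("PhantomTruth:\n")
  cat("  cell", format(maskArea(x$cellMask), digits = 4), "um^2, rim",
      format(maskArea(x$rimMask), digits = 4), "um^2, ICD",
      format(maskArea(x$icdMask), digits = 4), "um^2\n")
  cat("  lateral enrichment", x$trueLateralEnrichment,
      "| ICD enrichment", x$trueIcdEnrichment, "\n")
  cat("  clusters:", nrow(x$clusterTable), "planted, density",
      format(x$trueClusterDensityPct, digits = 4), "%\n")
  invisible(x)
}
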