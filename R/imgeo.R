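# Image geometry: stacks, masks, projections, reslicing, background.
#
# Coordinate convention: pixel indices are 1-based in R, but physically the
# i-th pixel along an axis spans ((i-1)*pitch, i*pitch] with its center at
# (i - 0.5) * pitch. All rasterization is center-based.

#' Construct an ImageStack
#'
#' @param voxels numeric array `(ny, nx, nz, nchannel)`; a 3-D array is
#'   treated as a single channel, a matrix as a single plane and channel.
#' @param pixelXY in-plane pixel pitch, um.
#' @param zStep z spacing, um.
#' @param channelNames optional channel names; defaults to `ch1`, `ch2`, ...
#' @return an [ImageStack-class].
#' @examples
#' stk <- imageStack(array(runif(4 * 5 * 3 * 2), c(4, 5, 3, 2)),
#'                   pixelXY = 0.1, zStep = 0.3)
#' @export
imageStack <- function(voxels, pixelXY, zStep, channelNames = NULL) {
  d <- dim(voxels)
  if (is.null(d) || length(d) == 2L) voxels <- array(voxels, c(dim(as.matrix(voxels)), 1L, 1L))
  else if (length(d) == 3L) voxels <- array(voxels, c(d, 1L))
  if (is.null(channelNames)) {
    channelNames <- paste0("ch", seq_len(dim(voxels)[4]))
  }
  new("ImageStack", voxels = voxels, pixelXY = pixelXY, zStep = zStep,
      channelNames = as.character(channelNames))
}

#' Construct a RegionMask
#'
#' @param mask logical matrix or 3-D array (numeric input is coerced with
#'   `!= 0`).
#' @param pixelDims physical pixel dimensions along each axis, um. A single
#'   value is recycled (isotropic pixels).
#' @return a [RegionMask-class].
#' @export
regionMask <- function(mask, pixelDims) {
  m <- array(mask != 0, dim(mask))
  nd <- length(dim(m))
  if (length(pixelDims) == 1L) pixelDims <- rep(pixelDims, nd)
  new("RegionMask", mask = m, pixelDims = as.numeric(pixelDims))
}

#' Rasterize a polygonal contour into a RegionMask
#'
#' A pixel belongs to the region iff its center lies inside the polygon
#' (even-odd rule), matching how a hand-drawn ROI contour is converted to a
#' pixel mask.
#'
#' @param verticesUm two-column matrix of polygon vertices `(x, y)` in um.
#' @param planeShape `c(ny, nx)` of the target plane in pixels.
#' @param pixelXY pixel pitch, um.
#' @return a [RegionMask-class] over the plane.
#' @examples
#' rect <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' m <- maskFromContour(rect, planeShape = c(10, 10), pixelXY = 0.1)
#' maskArea(m)  # 1 um^2
#' @export
maskFromContour <- function(verticesUm, planeShape, pixelXY) {
  verticesUm <- as.matrix(verticesUm)
  if (nrow(verticesUm) < 3L) stop("a polygon needs at least 3 vertices")
  # reject degenerate (zero-area) polygons via the shoelace formula
  vx <- verticesUm[, 1]; vy <- verticesUm[, 2]
  a2 <- abs(sum(vx * c(vy[-1], vy[1]) - c(vx[-1], vx[1]) * vy))
  if (a2 == 0) stop("degenerate polygon (zero area)")
  if (any(verticesUm < 0) || any(vx > planeShape[2] * pixelXY) ||
      any(vy > planeShape[1] * pixelXY)) {
    stop("polygon vertices fall outside the frame")
  }
  ny <- planeShape[1]; nx <- planeShape[2]
  cx <- (seq_len(nx) - 0.5) * pixelXY
  cy <- (seq_len(ny) - 0.5) * pixelXY
  px <- rep(cx, each = ny)
  py <- rep(cy, times = nx)
  inside <- pointsInPolygon(px, py, vx, vy)
  regionMask(matrix(inside, ny, nx), pixelXY)
}

#' Membrane rim mask by Euclidean distance to the cell exterior
#'
#' Selects the pixels of a cell mask whose Euclidean distance (in um, between
#' pixel centers) to the nearest outside-cell pixel is at most `widthUm` --
#' the "area within 1 um from the cellular contour" used for lateral-surface
#' quantification. A width of 0 returns an empty mask.
#'
#' @param cell a 2-D [RegionMask-class] of the cell; must not be empty.
#' @param widthUm rim width, um, >= 0.
#' @return a [RegionMask-class], subset of `cell`.
#' @export
rimMask <- function(cell, widthUm) {
  stopifnot(is(cell, "RegionMask"), length(dim(cell@mask)) == 2L)
  if (widthUm < 0) stop("widthUm must be >= 0")
  if (!any(cell@mask)) stop("cell mask is empty")
  if (cell@pixelDims[1] != cell@pixelDims[2]) {
    stop("rimMask requires isotropic in-plane pixels")
  }
  d <- EBImage::distmap(cell@mask) * cell@pixelDims[1]
  regionMask(cell@mask & d <= widthUm, cell@pixelDims)
}

#' Maximum-intensity z-projection
#'
#' Collapses a 3-D z-stack into a 2-D image by the per-pixel maximum over z,
#' the standard projection for puncta counting.
#'
#' @param stack an [ImageStack-class].
#' @param channel channel name or index.
#' @return numeric matrix `(ny, nx)`.
#' @export
zprojectMax <- function(stack, channel) {
  a <- getChannel(stack, channel)
  apply(a, c(1, 2), max)
}

#' Orthogonal YZ reslices at given x positions
#'
#' Extracts, for each requested physical x position, the YZ plane at the
#' nearest x pixel index -- the en-face view used for intercalated-disc
#' cluster analysis. Each plane is returned as a `(ny, nz)` matrix with a
#' `pixelDims` attribute `c(pixelXY, zStep)` um.
#'
#' @param stack an [ImageStack-class].
#' @param channel channel name or index.
#' @param xPositionsUm numeric vector of x positions, um.
#' @return named list of reslice matrices, one per position.
#' @export
resliceYZ <- function(stack, channel, xPositionsUm) {
  a <- getChannel(stack, channel)
  nx <- dim(a)[2]
  xmax <- nx * stack@pixelXY
  bad <- xPositionsUm < 0 | xPositionsUm > xmax
  if (any(bad)) {
    stop("x position(s) out of range [0, ", format(xmax), " um]: ",
         paste(format(xPositionsUm[bad]), collapse = ", "))
  }
  idx <- pmin(nx, pmax(1L, round(xPositionsUm / stack@pixelXY + 0.5)))
  out <- lapply(idx, function(i) {
    pl <- a[, i, , drop = FALSE]
    m <- matrix(pl, nrow = dim(a)[1])
    attr(m, "pixelDims") <- c(stack@pixelXY, stack@zStep)
    attr(m, "xIndex") <- as.integer(i)
    m
  })
  names(out) <- sprintf("x=%g um", xPositionsUm)
  out
}

#' Estimate background from a cell-free ROI
#'
#' Mean intensity over an explicit background mask. If a cell mask is given,
#' overlap between the two is an error: background must come from a
#' cell-free area.
#'
#' @param image numeric matrix.
#' @param bgMask a non-empty [RegionMask-class] on the same plane.
#' @param cellMask optional [RegionMask-class]; must be disjoint from
#'   `bgMask`.
#' @return mean background intensity (scalar).
#' @export
estimateBackground <- function(image, bgMask, cellMask = NULL) {
  stopifnot(is(bgMask, "RegionMask"))
  if (!any(bgMask@mask)) stop("background mask is empty")
  if (!identical(dim(image), dim(bgMask@mask))) {
    stop("image and background mask shapes differ")
  }
  if (!is.null(cellMask) && any(bgMask@mask & cellMask@mask)) {
    stop("background mask overlaps the cell mask")
  }
  mean(image[bgMask@mask])
}

#' Write an ImageStack to per-channel TIFF files with a JSON sidecar
#'
#' Each channel becomes `<prefix>_<channel>.tif` (one page per z-plane,
#' 32-bit float, intensities rescaled to `[0, 1]`); pixel sizes, channel
#' names and the intensity scale are recorded in `<prefix>.json` so that
#' [readImageStack()] restores the stack losslessly.
#'
#' @param stack an [ImageStack-class].
#' @param prefix path prefix for the output files.
#' @return invisibly, the sidecar path.
#' @export
writeImageStack <- function(stack, prefix) {
  d <- dim(stack@voxels)
  scale <- max(stack@voxels, 1e-12)
  files <- character(d[4])
  for (ci in seq_len(d[4])) {
    pages <- lapply(seq_len(d[3]), function(zi) stack@voxels[, , zi, ci] / scale)
    files[ci] <- paste0(prefix, "_", stack@channelNames[ci], ".tif")
    tiff::writeTIFF(pages, files[ci], bits.per.sample = 32L)
  }
  meta <- list(
    pixelXYUm = stack@pixelXY, zStepUm = stack@zStep,
    channelNames = stack@channelNames, intensityScale = scale,
    files = basename(files)
  )
  sidecar <- paste0(prefix, ".json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read an ImageStack written by [writeImageStack()]
#'
#' @param prefix the path prefix used when writing.
#' @param pixelXY,zStep optional overrides for the recorded pixel sizes, um.
#' @return an [ImageStack-class].
#' @export
readImageStack <- function(prefix, pixelXY = NULL, zStep = NULL) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  dir <- dirname(prefix)
  chans <- lapply(meta$files, function(f) {
    pages <- tiff::readTIFF(file.path(dir, f), all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, c(dim(pages[[1]]), length(pages)))
    for (zi in seq_along(pages)) arr[, , zi] <- pages[[zi]]
    arr * meta$intensityScale
  })
  vox <- array(0, c(dim(chans[[1]]), length(chans)))
  for (ci in seq_along(chans)) vox[, , , ci] <- chans[[ci]]
  imageStack(vox,
             pixelXY = if (is.null(pixelXY)) meta$pixelXYUm else pixelXY,
             zStep = if (is.null(zStep)) meta$zStepUm else zStep,
             channelNames = meta$channelNames)
}
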