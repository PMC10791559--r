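# Shared fixtures: small phantoms (for runtime) and independent oracles.

# Small whole-cell phantom, optics and noise off unless overridden.
tinySpec <- function(...) {
  args <- utils::modifyList(
    list(cellLengthUm = 30, cellWidthUm = 12, cellHeightUm = 0.9,
         applyPsf = FALSE, applyNoise = FALSE, seed = 1L),
    list(...)
  )
  do.call(phantomSpec, args)
}

# Small cluster-mode phantom (50-nm isotropic voxels).
tinyClusterSpec <- function(...) {
  args <- utils::modifyList(
    list(cellLengthUm = 20, cellWidthUm = 10, cellHeightUm = 0.25,
         pixelXYNm = 50, zStepNm = 50, psfFwhmZNm = 100,
         clusterDensityPct = 5, clusterRadiusUm = 0.25,
         clusterIntensity = 4, applyPsf = FALSE, applyNoise = FALSE,
         seed = 1L),
    list(...)
  )
  do.call(phantomSpec, args)
}

# O(n^2) brute-force oracle: per-pixel Euclidean distance (um) from each
# in-mask pixel to the nearest complement pixel.
bruteRim <- function(mask, widthUm, px) {
  ny <- nrow(mask); nx <- ncol(mask)
  out <- matrix(FALSE, ny, nx)
  outside <- which(!mask, arr.ind = TRUE)
  for (k in which(mask)) {
    iy <- (k - 1) %% ny + 1
    ix <- (k - 1) %/% ny + 1
    d2 <- (outside[, 1] - iy)^2 + (outside[, 2] - ix)^2
    out[iy, ix] <- sqrt(min(d2)) * px <= widthUm
  }
  out
}

# Queue-based 8-connected flood-fill labeling oracle.
floodLabel <- function(fg) {
  ny <- nrow(fg); nx <- ncol(fg)
  lab <- matrix(0L, ny, nx)
  nextLab <- 0L
  for (start in which(fg)) {
    if (lab[start] > 0L) next
    nextLab <- nextLab + 1L
    queue <- start
    lab[start] <- nextLab
    while (length(queue)) {
      k <- queue[1]; queue <- queue[-1]
      iy <- (k - 1) %% ny + 1
      ix <- (k - 1) %/% ny + 1
      for (dy in -1:1) for (dx in -1:1) {
        jy <- iy + dy; jx <- ix + dx
        if (jy < 1 || jy > ny || jx < 1 || jx > nx) next
        j <- (jx - 1) * ny + jy
        if (fg[j] && lab[j] == 0L) {
          lab[j] <- nextLab
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# Random blob mask: union of a few discs on a small frame.
randomBlobMask <- function(ny = 28, nx = 28, nBlobs = 3) {
  m <- matrix(FALSE, ny, nx)
  for (i in seq_len(nBlobs)) {
    cy <- runif(1, 5, ny - 4); cx <- runif(1, 5, nx - 4)
    r <- runif(1, 2, 6)
    yy <- matrix(seq_len(ny), ny, nx)
    xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    m <- m | ((yy - cy)^2 + (xx - cx)^2 <= r^2)
  }
  # keep the mask off the frame border so the complement is well defined
  m[c(1, ny), ] <- FALSE
  m[, c(1, nx)] <- FALSE
  m
}

# Build a stack with an en-face ICD band at one x index and planted target
# clusters (squares) in that YZ plane; returns the stack and the truth.
enFaceClusterStack <- function(xIndex = 10, nz = 40, ny = 40, nx = 20,
                               px = 0.05, squares = list(c(10, 10), c(25, 20)),
                               side = 4, intensity = 5) {
  target <- array(0.1, c(ny, nx, nz))
  ncad <- array(0.1, c(ny, nx, nz))
  icdPlane <- matrix(FALSE, ny, nz)
  icdPlane[5:(ny - 4), 5:(nz - 4)] <- TRUE
  ncad[, xIndex, ][icdPlane] <- 2
  clusterPx <- 0L
  for (sq in squares) {
    ys <- sq[1]:(sq[1] + side - 1L)
    zs <- sq[2]:(sq[2] + side - 1L)
    target[ys, xIndex, zs] <- intensity
    clusterPx <- clusterPx + side^2
  }
  stack <- imageStack(
    array(c(target, ncad), c(ny, nx, nz, 2)),
    pixelXY = px, zStep = px, channelNames = c("target", "ncad"))
  list(stack = stack, icdPlane = icdPlane, clusterPx = clusterPx,
       nSquares = length(squares), side = side, intensity = intensity,
       xIndex = xIndex, px = px)
}
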