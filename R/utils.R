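# Internal numerical helpers shared across modules.

# Evaluate `code` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched (generators must not perturb user randomness).
withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Normalized 1-D Gaussian kernel, sigma in pixels, truncated at 4 sigma.
gaussKernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Convolve a 1-D kernel along one margin of a 2-/3-D array with edge
# replication, so uniform regions stay uniform up to the border.
convolveAxis <- function(arr, kernel, axis) {
  nk <- length(kernel)
  if (nk == 1L) return(arr)
  r <- (nk - 1L) %/% 2L
  d <- dim(arr)
  nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  # replicate-pad along the convolution axis
  mp <- rbind(
    m[rep(1L, r), , drop = FALSE],
    m,
    m[rep(nrow(m), r), , drop = FALSE]
  )
  # stats::filter runs the kernel column-wise; interior rows are exact
  f <- stats::filter(mp, kernel, method = "convolution", sides = 2)
  out <- matrix(as.numeric(f[(r + 1L):(r + nrow(m)), ]), nrow = nrow(m))
  dim(out) <- da
  aperm(out, order(perm))
}

# Separable anisotropic Gaussian blur of a (y, x, z) array; FWHMs and pixel
# pitches in the same units. FWHM = 2 sqrt(2 ln 2) sigma ~= 2.3548 sigma.
blurStack <- function(arr, fwhmXY, fwhmZ, pixelXY, zStep) {
  sigXY <- fwhmXY / 2.3548 / pixelXY
  sigZ <- fwhmZ / 2.3548 / zStep
  k <- gaussKernel1d(sigXY)
  out <- convolveAxis(arr, k, 1L)
  out <- convolveAxis(out, k, 2L)
  if (dim(arr)[3] > 1L) out <- convolveAxis(out, gaussKernel1d(sigZ), 3L)
  out
}

# 8-connected labeling of a logical matrix by iterative minimum-label
# propagation (EBImage::bwlabel is 4-connected, which would split clusters
# touching only at corners). Labels are relabeled to contiguous 1..n.
label8 <- function(fg) {
  stopifnot(is.logical(fg), length(dim(fg)) == 2L)
  ny <- nrow(fg); nx <- ncol(fg)
  lab <- matrix(0L, ny, nx)
  lab[fg] <- seq_len(sum(fg))
  if (!any(fg)) return(lab)
  big <- sum(fg) + 1L
  l <- matrix(big, ny, nx)
  l[fg] <- lab[fg]
  shift <- function(m, dy, dx) {
    out <- matrix(big, ny, nx)
    ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
    ok_y <- ys >= 1L & ys <= ny; ok_x <- xs >= 1L & xs <= nx
    out[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
    out
  }
  repeat {
    nb <- l
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0L && dx == 0L) next
      nb <- pmin(nb, shift(l, dy, dx))
    }
    nb[!fg] <- big
    upd <- fg & (nb < l)
    if (!any(upd)) break
    l[upd] <- nb[upd]
  }
  l[!fg] <- 0L
  labs <- sort(unique(l[l > 0L]))
  lab <- matrix(0L, ny, nx)
  lab[fg] <- match(l[fg], labs)
  lab
}

# Otsu threshold over an arbitrary pixel vector: rescale to [0, 1], run
# EBImage::otsu on the values packed as an image, map back.
otsuThreshold <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  u <- (v - rng[1]) / diff(rng)
  t01 <- EBImage::otsu(EBImage::Image(matrix(u, nrow = 1L)), range = c(0, 1))
  rng[1] + t01 * diff(rng)
}

# Even-odd point-in-polygon test, vectorized over query points.
pointsInPolygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Standard error of the mean.
se <- function(x) stats::sd(x) / sqrt(length(x))
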