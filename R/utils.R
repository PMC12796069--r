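# Internal numeric / image helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

logspace <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))

#' 3D connected components
#'
#' Labels connected components of a logical 3D mask. Components are numbered
#' 1, 2, ... in decreasing voxel count; background is 0.
#'
#' @param mask logical 3D array.
#' @param connectivity 6 (face) or 26 (face+edge+corner) neighborhood.
#' @return integer array of labels with the same dimensions as `mask`.
#' @export
connectedComponents <- function(mask, connectivity = 26) {
  stopifnot(length(dim(mask)) == 3L)
  .cc_label3d(as.logical(mask), as.integer(dim(mask)),
              as.integer(connectivity))
}

#' Euclidean distance transform (mm)
#'
#' Exact Euclidean distance from every voxel to the nearest `TRUE` voxel,
#' in millimetres, honoring anisotropic voxel spacing. `Inf` when the mask
#' is empty.
#'
#' @param mask logical 3D array.
#' @param spacing voxel size in mm (length 3).
#' @return numeric array of distances (mm).
#' @export
distanceTransform <- function(mask, spacing) {
  stopifnot(length(dim(mask)) == 3L, length(spacing) == 3L)
  sqrt(.edt3d_sq(as.logical(mask), as.integer(dim(mask)),
                 as.numeric(spacing)))
}

# Shift a 3D array by integer offsets, zero-filling the exposed border.
shift3d <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(if (is.logical(a)) FALSE else 0, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  if (length(sx) < 1 || length(sy) < 1 || length(sz) < 1) return(out)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

# 3D binary dilation/erosion with a box (26-neighborhood) structuring
# element of radius r voxels.
dilate3d <- function(mask, r = 1L) {
  out <- mask
  for (i in seq_len(r)) {
    acc <- out
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      acc <- acc | shift3d(out, dx, dy, dz)
    }
    out <- acc
  }
  out
}

erode3d <- function(mask, r = 1L) !dilate3d(!mask, r)

close3d <- function(mask, r = 1L) erode3d(dilate3d(mask, r), r)

# Separable Gaussian blur of a 3D array, FWHM in mm per axis.
# Implemented as a banded convolution matrix per axis applied by matrix
# multiplication (kernels renormalized at the borders).
gaussBlur3d <- function(a, fwhm_mm, spacing) {
  if (all(fwhm_mm <= 0)) return(a)
  d <- dim(a)
  if (length(fwhm_mm) == 1L) fwhm_mm <- rep(fwhm_mm, 3L)
  kmat <- function(n, fwhm, h) {
    if (fwhm <= 0) return(diag(n))
    sigma <- fwhm / (2 * sqrt(2 * log(2))) / h # in voxels
    half <- max(1L, ceiling(3 * sigma))
    w <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
    K <- matrix(0, n, n)
    for (j in seq_len(n)) {
      idx <- (j - half):(j + half)
      ok <- idx >= 1 & idx <= n
      K[idx[ok], j] <- w[ok] / sum(w[ok])
    }
    K
  }
  Kx <- kmat(d[1], fwhm_mm[1], spacing[1])
  Ky <- kmat(d[2], fwhm_mm[2], spacing[2])
  Kz <- kmat(d[3], fwhm_mm[3], spacing[3])
  m <- Kx %*% matrix(a, d[1], d[2] * d[3]) # along x
  a <- array(m, d)
  a <- aperm(a, c(2, 1, 3)) # y first
  m <- Ky %*% matrix(a, d[2], d[1] * d[3])
  a <- aperm(array(m, d[c(2, 1, 3)]), c(2, 1, 3))
  a <- aperm(a, c(3, 1, 2)) # z first
  m <- Kz %*% matrix(a, d[3], d[1] * d[2])
  aperm(array(m, d[c(3, 1, 2)]), c(2, 3, 1))
}

# Trilinear interpolation of 3D array `a` at voxel coordinates (1-based,
# possibly fractional) given as an n x 3 matrix. Outside the grid -> `fill`.
trilinear <- function(a, coords, fill = 0) {
  d <- dim(a)
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  inside <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out <- rep(fill, nrow(coords))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  x0 <- pmin(pmax(floor(x), 1), d[1] - 1); fx <- x - x0
  y0 <- pmin(pmax(floor(y), 1), d[2] - 1); fy <- y - y0
  z0 <- pmin(pmax(floor(z), 1), d[3] - 1); fz <- z - z0
  # handle coords exactly on the upper boundary
  fx <- pmin(pmax(fx, 0), 1); fy <- pmin(pmax(fy, 0), 1); fz <- pmin(pmax(fz, 0), 1)
  idx <- function(i, j, k) ((k - 1) * d[2] + (j - 1)) * d[1] + i
  v <- a[idx(x0, y0, z0)] * (1 - fx) * (1 - fy) * (1 - fz) +
    a[idx(x0 + 1, y0, z0)] * fx * (1 - fy) * (1 - fz) +
    a[idx(x0, y0 + 1, z0)] * (1 - fx) * fy * (1 - fz) +
    a[idx(x0 + 1, y0 + 1, z0)] * fx * fy * (1 - fz) +
    a[idx(x0, y0, z0 + 1)] * (1 - fx) * (1 - fy) * fz +
    a[idx(x0 + 1, y0, z0 + 1)] * fx * (1 - fy) * fz +
    a[idx(x0, y0 + 1, z0 + 1)] * (1 - fx) * fy * fz +
    a[idx(x0 + 1, y0 + 1, z0 + 1)] * fx * fy * fz
  out[inside] <- v
  out
}

# Nearest-neighbour lookup at fractional voxel coordinates.
nearestNeighbour <- function(a, coords, fill = 0) {
  d <- dim(a)
  i <- round(coords[, 1]); j <- round(coords[, 2]); k <- round(coords[, 3])
  inside <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  out <- rep(fill, nrow(coords))
  out[inside] <- a[cbind(i[inside], j[inside], k[inside])]
  out
}

# World (mm) coordinates of every voxel centre: index (0-based) * spacing.
voxelCoordsMm <- function(dim3, spacing) {
  xs <- (seq_len(dim3[1]) - 1) * spacing[1]
  ys <- (seq_len(dim3[2]) - 1) * spacing[2]
  zs <- (seq_len(dim3[3]) - 1) * spacing[3]
  list(x = xs, y = ys, z = zs)
}

# Dice overlap of two logical masks.
#' Dice overlap coefficient of two masks
#' @param a,b logical arrays of equal dimension.
#' @return Dice coefficient between 0 and 1; NA if both masks are empty.
#' @export
diceCoefficient <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(NA_real_)
  2 * sum(a & b) / (sa + sb)
}

# Per-slice 2D hole filling (slices along the 3rd axis) via EBImage.
fillSlices <- function(mask) {
  d <- dim(mask)
  filled <- EBImage::fillHull(EBImage::Image(array(as.numeric(mask), d)))
  array(as.numeric(filled) > 0.5, d)
}
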