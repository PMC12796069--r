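# Short-axis reorientation, ventricular myocardium segmentation by
# circumferential profiling, cavity extraction by the 1.3 cm distance
# rule, and chamber timing statistics.

#' Short-axis reorientation transform
#'
#' Estimates the heart's long axis as the principal eigenvector of the
#' second-moment tensor of the largest connected high-V_A component on the
#' left-ventricular side (the component containing the most
#' arterial-cluster voxels), and builds a rigid transform that resamples
#' the native grid into a short-axis grid of the same shape and spacing
#' with the long axis along +z and the LV blood centroid at the grid
#' centre.
#'
#' @param kmaps a [KineticMaps-class] (the V_A image is used).
#' @param inputs the [InputFunctions-class] carrying the arterial-cluster
#'   membership.
#' @param va_thresh V_A threshold defining blood components.
#' @return list of class `ShortAxisTransform`: rotation `Q` (world mm,
#'   det +1), `centerNative` (mm), `centerSa` (mm), `dim`, `spacing`, and
#'   the estimated `longAxis` (unit vector, native frame).
#' @export
reorientShortAxis <- function(kmaps, inputs, va_thresh = 0.5) {
  va <- kmaps@va
  high <- !is.na(va) & va > va_thresh
  if (!any(high))
    stop("segmentation failure: no high-V_A blood component found")
  cc <- connectedComponents(high, 26)
  art <- array(FALSE, dim(va))
  art[!is.na(inputs@clusterLabels) &
        inputs@clusterLabels == inputs@arterialCluster] <- TRUE
  ncomp <- max(cc)
  counts <- vapply(seq_len(ncomp), function(l) sum(art[cc == l]), numeric(1))
  lv <- if (any(counts > 0)) which.max(counts) else 1L
  sp <- kmaps@spacing
  idx <- which(cc == lv, arr.ind = TRUE)
  P <- sweep(idx - 1, 2, sp, `*`)
  ctr <- colMeans(P)
  S <- stats::cov(P)
  ev <- eigen(S, symmetric = TRUE)
  v1 <- ev$vectors[, 1] # long axis (largest variance)
  v2 <- ev$vectors[, 2]
  if (v1[3] < 0) v1 <- -v1
  if (v2[1] < 0) v2 <- -v2
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2], # v3 = v1 x v2 -> right-handed
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  Q <- rbind(x = v2, y = v3, z = v1) # world -> short-axis rotation
  d <- dim(va)
  structure(list(Q = Q, centerNative = ctr,
                 centerSa = (d - 1) * sp / 2, dim = d, spacing = sp,
                 longAxis = v1),
            class = "ShortAxisTransform")
}

#' Resample a volume through a short-axis transform
#'
#' @param arr 3D array on the source grid.
#' @param transform a `ShortAxisTransform` from [reorientShortAxis()].
#' @param interp "linear" (images) or "nearest" (masks/labels).
#' @param direction "forward" (native to short-axis) or "inverse".
#' @param fill value outside the source grid.
#' @return resampled 3D array.
#' @export
applyTransform <- function(arr, transform, interp = c("linear", "nearest"),
                           direction = c("forward", "inverse"), fill = 0) {
  interp <- match.arg(interp)
  direction <- match.arg(direction)
  tr <- transform
  d <- tr$dim
  sp <- tr$spacing
  cm <- voxelCoordsMm(d, sp)
  Pt <- cbind(rep(cm$x, times = d[2] * d[3]),
              rep(rep(cm$y, each = d[1]), times = d[3]),
              rep(cm$z, each = d[1] * d[2]))
  if (direction == "forward") {
    # target = short-axis grid; source = native
    src <- sweep(Pt, 2, tr$centerSa) %*% tr$Q # t(Q^T x) = x Q
    src <- sweep(src, 2, tr$centerNative, `+`)
  } else {
    src <- sweep(Pt, 2, tr$centerNative) %*% t(tr$Q)
    src <- sweep(src, 2, tr$centerSa, `+`)
  }
  coords <- sweep(src, 2, sp, `/`) + 1
  vals <- if (interp == "linear") trilinear(arr, coords, fill)
  else nearestNeighbour(arr, coords, fill)
  out <- array(vals, d)
  if (is.logical(arr)) out <- array(as.logical(out), d)
  out
}

# Bilinear sampling of one slice at (possibly fractional) voxel coords.
bilinearSlice <- function(slice, xi, yi, fill = 0) {
  d <- dim(slice)
  out <- rep(fill, length(xi))
  inside <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2]
  x <- xi[inside]; y <- yi[inside]
  x0 <- pmin(pmax(floor(x), 1), d[1] - 1); fx <- pmin(pmax(x - x0, 0), 1)
  y0 <- pmin(pmax(floor(y), 1), d[2] - 1); fy <- pmin(pmax(y - y0, 0), 1)
  v <- slice[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    slice[cbind(x0 + 1, y0)] * fx * (1 - fy) +
    slice[cbind(x0, y0 + 1)] * (1 - fx) * fy +
    slice[cbind(x0 + 1, y0 + 1)] * fx * fy
  out[inside] <- v
  out
}

#' Segment the ventricular myocardium by circumferential profiling
#'
#' Works on short-axis maps. Per slice, the cavity centre is the centroid
#' of the largest high-V_A (LV) or high-V_RV (RV) region; 36 radial
#' profiles of the PTF image are sampled around it, the myocardial wall is
#' located at the first sufficiently prominent PTF ridge along each
#' profile, and the inner/outer wall edges are placed at half-maximum.
#' The per-slice annulus between the interpolated edges is rasterized,
#' slices are stacked, the mask is morphologically closed (1-voxel
#' radius) and the largest connected component is kept.
#'
#' @param kmapsSA a [KineticMaps-class] resampled to short axis.
#' @param side "LV" (V_A-guided) or "RV" (V_RV-guided).
#' @param center_thresh blood threshold for the per-slice centre.
#' @param n_angles number of circumferential profiles per slice.
#' @param r_max_mm,r_step_mm radial sampling extent and step.
#' @param ridge_frac a local maximum must reach this fraction of the
#'   profile maximum to count as the wall ridge.
#' @param ptf_min absolute minimum ridge PTF (g/mL).
#' @param min_slices minimum number of slices with a detectable cavity.
#' @return logical 3D short-axis mask of the myocardium.
#' @export
segmentMyocardium <- function(kmapsSA, side = c("LV", "RV"),
                              center_thresh = 0.5, n_angles = 36L,
                              r_max_mm = 60, r_step_mm = 1,
                              ridge_frac = 0.5, ptf_min = 0.1,
                              min_slices = 3L) {
  side <- match.arg(side)
  guide <- if (side == "LV") kmapsSA@va else kmapsSA@vrv
  ptf <- kmapsSA@ptf
  ptf[is.na(ptf)] <- 0
  guide[is.na(guide)] <- 0
  d <- dim(ptf)
  sp <- kmapsSA@spacing
  mask <- array(FALSE, d)
  theta <- (seq_len(n_angles) - 1) * 2 * pi / n_angles
  rr <- seq(0, r_max_mm, by = r_step_mm)
  nslices <- 0L
  for (z in seq_len(d[3])) {
    gsl <- guide[, , z] > center_thresh
    if (sum(gsl) < 4) next
    lab <- EBImage::bwlabel(EBImage::Image(gsl * 1))
    tab <- tabulate(as.integer(lab))
    big <- which.max(tab)
    reg <- which(as.integer(lab) == big)
    if (length(reg) < 4) next
    cx <- mean((reg - 1) %% d[1] + 1)
    cy <- mean((reg - 1) %/% d[1] + 1)
    nslices <- nslices + 1L
    psl <- ptf[, , z]
    rin <- rep(NA_real_, n_angles)
    rout <- rep(NA_real_, n_angles)
    for (a in seq_len(n_angles)) {
      xi <- cx + rr * cos(theta[a]) / sp[1]
      yi <- cy + rr * sin(theta[a]) / sp[2]
      v <- bilinearSlice(psl, xi, yi)
      vmax <- max(v)
      if (vmax < ptf_min) next
      n <- length(v)
      locmax <- which(v >= c(-Inf, v[-n]) & v >= c(v[-1], -Inf) &
                        v >= max(ridge_frac * vmax, ptf_min))
      if (length(locmax) == 0) next
      i0 <- locmax[1]
      half <- v[i0] / 2
      iIn <- i0
      while (iIn > 1 && v[iIn - 1] >= half) iIn <- iIn - 1
      iOut <- i0
      while (iOut < n && v[iOut + 1] >= half) iOut <- iOut + 1
      rin[a] <- rr[iIn]
      rout[a] <- rr[iOut]
    }
    if (all(is.na(rin))) next
    # rasterize the annulus between the per-angle edges
    ij <- which(array(TRUE, d[1:2]), arr.ind = TRUE)
    dxm <- (ij[, 1] - cx) * sp[1]
    dym <- (ij[, 2] - cy) * sp[2]
    rm <- sqrt(dxm^2 + dym^2)
    am <- atan2(dym, dxm) %% (2 * pi)
    bin <- pmin(floor(am / (2 * pi / n_angles)) + 1, n_angles)
    ok <- !is.na(rin[bin]) & rm >= rin[bin] & rm <= rout[bin]
    sl <- array(FALSE, d[1:2])
    sl[ij[ok, , drop = FALSE]] <- TRUE
    mask[, , z] <- sl
  }
  if (nslices < min_slices)
    stop("segmentation failure: fewer than ", min_slices,
         " short-axis slices with a detectable ", side, " cavity")
  if (!any(mask))
    stop("segmentation failure: no ", side,
         " myocardial wall found by circumferential profiling")
  mask <- close3d(mask, 1L)
  cc <- connectedComponents(mask, 26)
  cc == 1
}

#' Extract the ventricular cavities by the 1.3 cm rule
#'
#' A cavity is every voxel inside the respective myocardial ring (per-slice
#' filled interior) whose Euclidean distance to the nearest myocardial
#' voxel is at least `margin_mm` (default 13 mm, twice an assumed PET
#' resolution of 6.5 mm FWHM). Distances are in world units and honor
#' anisotropic voxels. When a blood mask is supplied the cavity is
#' restricted to it.
#'
#' @param myoLv,myoRv logical myocardium masks (short-axis grid).
#' @param spacing voxel size (mm).
#' @param blood optional logical blood mask on the same grid.
#' @param margin_mm cavity margin (mm).
#' @return list with logical masks `lv_cavity` and `rv_cavity`.
#' @export
extractCavities <- function(myoLv, myoRv, spacing, blood = NULL,
                            margin_mm = 13) {
  one <- function(myo) {
    interior <- fillSlices(myo) & !myo
    dist <- distanceTransform(myo, spacing)
    cav <- interior & dist >= margin_mm
    if (!is.null(blood)) cav <- cav & blood
    if (!any(cav))
      warning("empty cavity after the ", margin_mm, " mm margin")
    cav
  }
  list(lv_cavity = one(myoLv), rv_cavity = one(myoRv))
}

#' Cavity timing and area statistics
#'
#' Extracts the mean TAC of each cavity, applies first-pass peak
#' extraction and stores the centroid times and areas as t_LV, t_RV,
#' AUC_LV and AUC_RV. AUC_LV subsequently becomes the AUC normalization
#' reference.
#'
#' @param series a [DynamicSeries-class] (native grid).
#' @param lvCavity,rvCavity logical cavity masks on the native grid.
#' @return list of class `ChamberStats` with `t_lv`, `t_rv`, `auc_lv`,
#'   `auc_rv` and a `flags` character vector.
#' @export
chamberStats <- function(series, lvCavity, rvCavity) {
  if (!any(lvCavity)) stop("empty LV cavity mask")
  if (!any(rvCavity)) stop("empty RV cavity mask")
  d <- dim(seriesData(series))[1:3]
  flat <- matrix(seriesData(series), prod(d), nFrames(series))
  sch <- data.frame(start = frameStart(series),
                    duration = frameDuration(series))
  one <- function(mask) {
    tac <- colMeans(flat[which(mask), , drop = FALSE])
    p <- extractFirstPassPeak(tac, sch)
    if (is.null(p)) stop("no first-pass peak in cavity TAC")
    peakMetrics(p)
  }
  lv <- one(lvCavity)
  rv <- one(rvCavity)
  flags <- character(0)
  if (rv["t_mid"] >= lv["t_mid"])
    flags <- c(flags, "t_rv_not_before_t_lv")
  structure(list(t_lv = unname(lv["t_mid"]), t_rv = unname(rv["t_mid"]),
                 auc_lv = unname(lv["auc"]), auc_rv = unname(rv["auc"]),
                 flags = flags),
            class = "ChamberStats")
}

#' Left-ventricular outflow-tract axis
#'
#' Operationalized as the line from the LV-cavity centroid through the
#' centroid of the basal-most cavity slice (the extreme slice end with the
#' larger cavity cross-section), expressed in native world coordinates.
#'
#' @param lvCavitySA logical LV-cavity mask on the short-axis grid.
#' @param transform the `ShortAxisTransform` used to map back to native.
#' @return list with `point` (mm, native) and `direction` (unit vector).
#' @export
lvotAxis <- function(lvCavitySA, transform) {
  if (!any(lvCavitySA)) stop("empty LV cavity mask")
  sp <- transform$spacing
  idx <- which(lvCavitySA, arr.ind = TRUE)
  ctrSA <- colMeans(sweep(idx - 1, 2, sp, `*`))
  zs <- sort(unique(idx[, 3]))
  areaAt <- function(z) sum(idx[, 3] == z)
  basalZ <- if (areaAt(zs[length(zs)]) >= areaAt(zs[1]))
    zs[length(zs)] else zs[1]
  bidx <- idx[idx[, 3] == basalZ, , drop = FALSE]
  baseSA <- colMeans(sweep(bidx - 1, 2, sp, `*`))
  toNative <- function(p)
    as.numeric(transform$centerNative +
                 t(transform$Q) %*% (p - transform$centerSa))
  a <- toNative(ctrSA)
  b <- toNative(baseSA)
  u <- b - a
  u <- u / sqrt(sum(u^2))
  list(point = a, direction = u)
}
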