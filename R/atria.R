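# Atrial segmentation: timing gates on the blood mask, outflow-tract
# split of the aorta from the LA, tube detection for the SVC, and the
# final volume report.

# In-plane perimeter of a 2D mask by boundary-face counting with the
# pi/4 Manhattan correction (unbiased for digitized convex shapes).
slicePerimeter <- function(sl, pixel_mm) {
  d <- dim(sl)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  cross <- 0
  for (s in shifts) {
    sh <- array(FALSE, d)
    sx <- max(1, 1 + s[1]):min(d[1], d[1] + s[1])
    sy <- max(1, 1 + s[2]):min(d[2], d[2] + s[2])
    sh[sx, sy] <- sl[sx - s[1], sy - s[2]]
    cross <- cross + sum(sl & !sh) *
      (if (s[1] != 0) pixel_mm[2] else pixel_mm[1])
  }
  cross * pi / 4
}

# Distance (mm) of world points P (n x 3) from the line a + t*u.
distToLine <- function(P, a, u) {
  rel <- sweep(P, 2, a)
  along <- as.numeric(rel %*% u)
  sqrt(pmax(rowSums(rel^2) - along^2, 0))
}

#' Segment the left atrium and split off the aorta
#'
#' Candidate voxels are the blood mask with three eliminations: regions
#' with t_mid greater than t_LV plus the duration of two heartbeats,
#' regions with t_mid less than that of the lungs, and the LV cavity
#' (dilated by one voxel). The aorta is separated by removing voxels
#' within a cylinder around the LV outflow-tract axis, growing its radius
#' from `r0_mm` until the candidate splits into at least two connected
#' components of at least `min_component_ml` each; the component with the
#' lowest median t_mid is kept as the LA and the other components become
#' the aorta mask. If no split is achieved at `rmax_mm` the entire
#' candidate is returned as LA with a fallback flag.
#'
#' @param blood logical blood mask (native grid).
#' @param maps normalized [ParametricMaps-class].
#' @param stats `ChamberStats` from [chamberStats()].
#' @param t_lungs lung transit reference (s).
#' @param lvCavity logical LV-cavity mask (native grid).
#' @param lvot LV outflow-tract axis from [lvotAxis()].
#' @param heart_rate heart rate (bpm) defining the two-heartbeat gate.
#' @param min_component_ml minimum component size for a valid split (mL).
#' @param r0_mm,rmax_mm,rstep_mm cylinder growth schedule (mm).
#' @return list with logical masks `la`, `aorta` and a `flags` vector.
#' @export
segmentLeftAtrium <- function(blood, maps, stats, t_lungs, lvCavity, lvot,
                              heart_rate = 60, min_component_ml = 5,
                              r0_mm = 5, rmax_mm = 30, rstep_mm = 1) {
  stopifnot(heart_rate > 0)
  gate <- stats$t_lv + 2 * 60 / heart_rate
  tm <- maps@tmid
  cand <- blood & !is.na(tm) & tm <= gate & tm >= t_lungs &
    !dilate3d(lvCavity, 1L)
  if (!any(cand))
    stop("segmentation failure: empty left-heart candidate mask")
  sp <- maps@spacing
  voxMl <- prod(sp) / 1000
  idx <- which(cand)
  ai <- arrayInd(idx, dim(cand))
  dline <- distToLine(sweep(ai - 1, 2, sp, `*`), lvot$point,
                      lvot$direction)
  flags <- character(0)
  for (r in seq(r0_mm, rmax_mm, by = rstep_mm)) {
    keep <- array(FALSE, dim(cand))
    keep[idx[dline > r]] <- TRUE
    cc <- connectedComponents(keep, 26)
    sizes <- tabulate(cc[cc > 0])
    big <- which(sizes * voxMl >= min_component_ml)
    if (length(big) >= 2) {
      med <- vapply(big, function(l) median(tm[cc == l], na.rm = TRUE),
                    numeric(1))
      laLab <- big[which.min(med)]
      la <- cc == laLab
      aorta <- cand & !la # other components + removed cylinder voxels
      return(list(la = la, aorta = aorta, flags = flags))
    }
  }
  flags <- c(flags, "la_aorta_split_failed")
  warning("LV outflow-tract split failed up to ", rmax_mm,
          " mm; keeping the whole candidate as LA")
  list(la = cand, aorta = array(FALSE, dim(cand)), flags = flags)
}

#' Segment the right atrium and remove the superior vena cava
#'
#' Mirrors the left-atrial rule with t_RV: candidate voxels are the blood
#' mask minus regions later than t_RV plus two heartbeats, minus the RV
#' cavity (dilated one voxel) and minus the already-assigned LA/aorta.
#' The SVC is assumed to be a tube: scanning axial slices from the
#' superior end, a slice is tube-like when its candidate cross-section is
#' smaller than `tube_area_max_cm2` and has circularity
#' (4*pi*area/perimeter^2) above `tube_circ_min`; a maximal run of at
#' least `tube_min_run` consecutive tube-like slices contiguous with the
#' superior end is labeled SVC and removed. The RA is the largest
#' remaining connected component.
#'
#' @param blood logical blood mask.
#' @param maps normalized [ParametricMaps-class].
#' @param stats `ChamberStats`.
#' @param rvCavity logical RV-cavity mask (native grid).
#' @param la,aorta masks from [segmentLeftAtrium()].
#' @param heart_rate heart rate (bpm).
#' @param tube_area_max_cm2 maximum tube cross-section (cm^2).
#' @param tube_circ_min minimum tube circularity.
#' @param tube_min_run minimum consecutive tube-like slices.
#' @return list with logical masks `ra`, `svc` and a `flags` vector.
#' @export
segmentRightAtrium <- function(blood, maps, stats, rvCavity, la, aorta,
                               heart_rate = 60, tube_area_max_cm2 = 6,
                               tube_circ_min = 0.6, tube_min_run = 3L) {
  stopifnot(heart_rate > 0)
  gate <- stats$t_rv + 2 * 60 / heart_rate
  tm <- maps@tmid
  cand <- blood & !is.na(tm) & tm <= gate & !dilate3d(rvCavity, 1L) &
    !la & !aorta
  if (!any(cand))
    stop("segmentation failure: empty right-heart candidate mask")
  sp <- maps@spacing
  d <- dim(cand)
  pixA <- sp[1] * sp[2] / 100 # cm^2
  zAny <- which(apply(cand, 3, any))
  top <- max(zAny)
  svcZ <- integer(0)
  for (z in seq(top, min(zAny))) {
    sl <- cand[, , z]
    n <- sum(sl)
    if (n == 0) break
    area <- n * pixA
    per <- slicePerimeter(sl, sp[1:2])
    circ <- if (per > 0) 4 * pi * (area * 100) / per^2 else 0
    if (area < tube_area_max_cm2 && circ > tube_circ_min)
      svcZ <- c(svcZ, z)
    else break
  }
  svc <- array(FALSE, d)
  flags <- character(0)
  if (length(svcZ) >= tube_min_run) {
    svc[, , svcZ] <- cand[, , svcZ]
    cand <- cand & !svc
  } else svcZ <- integer(0)
  if (!any(cand))
    stop("segmentation failure: right-heart candidate empty after SVC removal")
  cc <- connectedComponents(cand, 26)
  ra <- cc == 1
  list(ra = ra, svc = svc, flags = flags)
}

#' Body surface area (Du Bois)
#'
#' \eqn{BSA = 0.007184 \cdot weight^{0.425} \cdot height^{0.725}} with
#' weight in kg and height in cm.
#'
#' @param height_cm height (cm).
#' @param weight_kg weight (kg).
#' @return BSA in m^2.
#' @examples bsaDuBois(170, 70)
#' @export
bsaDuBois <- function(height_cm, weight_kg) {
  if (height_cm <= 0 || weight_kg <= 0)
    stop("height and weight must be positive")
  0.007184 * weight_kg^0.425 * height_cm^0.725
}

#' Assemble the chamber label map
#'
#' Combines the segmented structure masks into a single integer label
#' volume with the fixed codes of [chamberLabelCodes()], resolving any
#' residual overlap by that priority order.
#'
#' @param masks named list of logical masks (names as in
#'   [chamberLabelCodes()]; missing structures allowed).
#' @param spacing voxel size (mm).
#' @param provenance named character vector ("auto"/"fallback").
#' @return a [ChamberLabelMap-class].
#' @export
buildChamberLabelMap <- function(masks, spacing,
                                 provenance = character(0)) {
  codes <- chamberLabelCodes()
  d <- dim(masks[[1]])
  lab <- array(0L, d)
  for (nm in names(codes)) {
    m <- masks[[nm]]
    if (is.null(m)) next
    lab[m & lab == 0L] <- codes[[nm]]
  }
  new("ChamberLabelMap", labels = lab, spacing = as.numeric(spacing),
      provenance = provenance)
}

#' Atrial volume report
#'
#' Volumes are voxel count times voxel volume; BSA indexing uses the
#' Du Bois formula. Non-positive height/weight skip the indexing (with a
#' warning) but volumes are still reported; an empty atrial label sets a
#' QC flag.
#'
#' @param labels a [ChamberLabelMap-class].
#' @param height_cm,weight_kg subject height (cm) and weight (kg); `NA`
#'   to skip BSA indexing.
#' @param stats `ChamberStats` (timing references carried into the
#'   report).
#' @param t_lungs lung transit reference (s).
#' @param flags additional QC flags collected upstream.
#' @return a [VolumeReport-class].
#' @export
atrialVolumeReport <- function(labels, height_cm = NA, weight_kg = NA,
                               stats, t_lungs, flags = character(0)) {
  voxMl <- voxelVolumeMl(labels)
  lav <- sum(labelMask(labels, "la")) * voxMl
  rav <- sum(labelMask(labels, "ra")) * voxMl
  if (lav == 0) flags <- c(flags, "empty_la")
  if (rav == 0) flags <- c(flags, "empty_ra")
  bsa <- NA_real_
  if (!is.na(height_cm) && !is.na(weight_kg)) {
    if (height_cm <= 0 || weight_kg <= 0) {
      warning("non-positive height/weight: BSA indexing skipped")
      flags <- c(flags, "invalid_bsa_inputs")
    } else bsa <- bsaDuBois(height_cm, weight_kg)
  }
  new("VolumeReport",
      lavMl = lav, ravMl = rav,
      laviMlM2 = if (is.na(bsa)) NA_real_ else lav / bsa,
      raviMlM2 = if (is.na(bsa)) NA_real_ else rav / bsa,
      bsaM2 = bsa, tLv = stats$t_lv, tRv = stats$t_rv, tLungs = t_lungs,
      aucLv = stats$auc_lv, flags = flags)
}
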