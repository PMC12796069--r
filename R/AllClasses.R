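#' @import methods
#' @importFrom stats approx kmeans quantile rnorm sd integrate aggregate median
#' @importFrom utils head tail write.csv read.csv
#' @useDynLib atriaPET, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("arrayOrNULL", c("array", "NULL"))

#' DynamicSeries: a 4D dynamic PET acquisition
#'
#' Container for a dynamic PET series: a 4D activity array (x, y, z, frame)
#' in kBq/mL together with the voxel spacing (mm) and the frame schedule
#' (start and duration of each time frame, seconds). The frame schedule must
#' start at 0 s and be contiguous (each frame starts where the previous one
#' ends); the 4th array dimension must match the number of frames.
#'
#' @slot data 4D numeric array (x, y, z, frame), activity in kBq/mL.
#' @slot spacing numeric length-3, voxel size in mm per axis.
#' @slot frameStart numeric, frame start times in seconds.
#' @slot frameDuration numeric, frame durations in seconds.
#'
#' @export
setClass("DynamicSeries",
  representation(
    data = "array",
    spacing = "numeric",
    frameStart = "numeric",
    frameDuration = "numeric"
  )
)

setValidity("DynamicSeries", function(object) {
  msg <- NULL
  if (length(dim(object@data)) != 4L)
    msg <- c(msg, "data must be a 4D array (x, y, z, frame)")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values (mm)")
  nf <- length(object@frameStart)
  if (length(object@frameDuration) != nf)
    msg <- c(msg, "frameStart and frameDuration lengths differ")
  if (length(dim(object@data)) == 4L && dim(object@data)[4] != nf)
    msg <- c(msg, "4th data dimension must equal the number of frames")
  if (nf > 0) {
    if (any(object@frameDuration <= 0))
      msg <- c(msg, "frame durations must be positive")
    if (abs(object@frameStart[1]) > 1e-9)
      msg <- c(msg, "frame schedule must start at 0 s")
    if (nf > 1) {
      gap <- object@frameStart[-1] -
        (object@frameStart[-nf] + object@frameDuration[-nf])
      if (any(abs(gap) > 1e-6))
        msg <- c(msg, "frame schedule must be contiguous and non-overlapping")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a DynamicSeries
#'
#' @param data 4D activity array (x, y, z, frame), kBq/mL.
#' @param spacing voxel size in mm (length 3).
#' @param frameStart frame start times (s).
#' @param frameDuration frame durations (s).
#' @return A validated [DynamicSeries-class] object.
#' @examples
#' s <- DynamicSeries(array(0, c(4, 4, 4, 2)), c(2, 2, 2), c(0, 5), c(5, 5))
#' nFrames(s)
#' @export
DynamicSeries <- function(data, spacing, frameStart, frameDuration) {
  new("DynamicSeries", data = data, spacing = as.numeric(spacing),
      frameStart = as.numeric(frameStart),
      frameDuration = as.numeric(frameDuration))
}

#' ParametricMaps: voxel-wise first-pass bolus maps
#'
#' Voxel-wise images derived from first-pass peak extraction: the bolus
#' centroid time t_mid (s), the raw area under the first-pass peak
#' (kBq.s/mL) and, once the left-ventricular reference is known, the AUC
#' normalized so that the LV blood pool has area 1. Voxels where no
#' first-pass peak was detected are flagged rather than zero-filled.
#'
#' @slot tmid 3D array of centroid times (s); NA where no peak.
#' @slot auc 3D array of raw first-pass AUC (kBq.s/mL); NA where no peak.
#' @slot detected logical 3D array, TRUE where a peak was found.
#' @slot aucNorm normalized AUC array, or NULL before normalization.
#' @slot aucReference LV-cavity reference AUC (kBq.s/mL), NA until set.
#' @slot spacing voxel size (mm).
#' @export
setClass("ParametricMaps",
  representation(
    tmid = "array",
    auc = "array",
    detected = "array",
    aucNorm = "arrayOrNULL",
    aucReference = "numeric",
    spacing = "numeric"
  ),
  prototype(aucNorm = NULL, aucReference = NA_real_)
)

setValidity("ParametricMaps", function(object) {
  msg <- NULL
  d <- dim(object@tmid)
  if (length(d) != 3L) msg <- c(msg, "tmid must be 3D")
  if (!identical(dim(object@auc), d)) msg <- c(msg, "auc dim mismatch")
  if (!identical(dim(object@detected), d))
    msg <- c(msg, "detected dim mismatch")
  if (!is.null(object@aucNorm) && !identical(dim(object@aucNorm), d))
    msg <- c(msg, "aucNorm dim mismatch")
  if (!is.null(object@aucNorm) && !is.finite(object@aucReference))
    msg <- c(msg, "aucNorm present but aucReference not set")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values")
  if (is.null(msg)) TRUE else msg
})

#' KineticMaps: single-tissue compartment model parameter images
#'
#' Voxel-wise parametric images from the basis-function fit of the
#' single-tissue compartment model for O-15 water: myocardial blood flow
#' (MBF, mL/g/min), perfusable tissue fraction (PTF, g/mL), arterial and
#' right-ventricular blood volume fractions (V_A, V_RV) and the weighted
#' residual sum of squares of the fit. Voxels outside the fitted mask are NA.
#'
#' @slot mbf,ptf,va,vrv,rss 3D arrays of fitted parameters (NA outside mask).
#' @slot fitted logical 3D array of voxels that were fitted.
#' @slot spacing voxel size (mm).
#' @export
setClass("KineticMaps",
  representation(
    mbf = "array", ptf = "array", va = "array", vrv = "array",
    rss = "array", fitted = "array", spacing = "numeric"
  )
)

setValidity("KineticMaps", function(object) {
  d <- dim(object@mbf)
  msg <- NULL
  if (length(d) != 3L) msg <- c(msg, "mbf must be 3D")
  for (s in c("ptf", "va", "vrv", "rss", "fitted"))
    if (!identical(dim(slot(object, s)), d))
      msg <- c(msg, paste(s, "dim mismatch"))
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values")
  if (is.null(msg)) TRUE else msg
})

#' InputFunctions: cluster-derived blood input functions
#'
#' Arterial (C_A) and venous (C_RV) whole-blood input functions obtained by
#' k-means cluster analysis of voxel time-activity curves, together with the
#' cluster structure needed by later stages (per-voxel cluster labels over
#' the candidate mask, mean raw TAC per cluster, mean raw AUC per cluster).
#'
#' @slot ca arterial input function, one value per frame (kBq/mL).
#' @slot crv venous input function (kBq/mL).
#' @slot frameMid frame mid-times (s).
#' @slot clusterLabels integer 3D array of cluster indices (NA outside the
#'   candidate mask).
#' @slot clusterMeans k x nframes matrix of mean raw TACs per cluster.
#' @slot clusterAUC mean raw first-pass AUC per cluster.
#' @slot clusterSize voxel count per cluster.
#' @slot arterialCluster,venousCluster selected cluster indices.
#' @export
setClass("InputFunctions",
  representation(
    ca = "numeric", crv = "numeric", frameMid = "numeric",
    clusterLabels = "array", clusterMeans = "matrix",
    clusterAUC = "numeric", clusterSize = "numeric",
    arterialCluster = "integer", venousCluster = "integer"
  )
)

setValidity("InputFunctions", function(object) {
  msg <- NULL
  nf <- length(object@frameMid)
  if (length(object@ca) != nf || length(object@crv) != nf)
    msg <- c(msg, "input function length must equal frame count")
  if (any(object@ca < -1e-6) || any(object@crv < -1e-6))
    msg <- c(msg, "input functions must be non-negative")
  if (ncol(object@clusterMeans) != nf)
    msg <- c(msg, "clusterMeans columns must equal frame count")
  k <- nrow(object@clusterMeans)
  if (length(object@clusterAUC) != k || length(object@clusterSize) != k)
    msg <- c(msg, "per-cluster vectors must have k entries")
  if (is.null(msg)) TRUE else msg
})

#' ChamberLabelMap: integer segmentation of the cardiac chambers
#'
#' Integer label volume for the eight segmented structures, with a fixed
#' legend: 1 LV myocardium, 2 RV myocardium, 3 LV cavity, 4 RV cavity,
#' 5 LA, 6 RA, 7 aorta, 8 SVC. Labels are pairwise disjoint by
#' construction. Per-structure provenance records whether a structure was
#' segmented automatically or by a documented fallback rule.
#'
#' @slot labels integer 3D array with codes 0 (background) and 1..8.
#' @slot spacing voxel size (mm).
#' @slot provenance named character vector, "auto" or "fallback" per
#'   structure.
#' @export
setClass("ChamberLabelMap",
  representation(labels = "array", spacing = "numeric",
                 provenance = "character")
)

#' Fixed structure label codes
#' @return Named integer vector mapping structure names to label codes.
#' @examples chamberLabelCodes()
#' @export
chamberLabelCodes <- function() {
  c(lv_myocardium = 1L, rv_myocardium = 2L, lv_cavity = 3L, rv_cavity = 4L,
    la = 5L, ra = 6L, aorta = 7L, svc = 8L)
}

setValidity("ChamberLabelMap", function(object) {
  msg <- NULL
  if (length(dim(object@labels)) != 3L) msg <- c(msg, "labels must be 3D")
  vals <- unique(as.integer(object@labels))
  if (!all(vals %in% c(0L, chamberLabelCodes())))
    msg <- c(msg, "labels must be 0 or one of the 8 structure codes")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values")
  if (is.null(msg)) TRUE else msg
})

#' VolumeReport: atrial volumes and chamber timing summary
#'
#' Final pipeline report: left and right atrial volume (mL), body surface
#' area (Du Bois, m^2), BSA-indexed volumes (mL/m^2), the chamber timing
#' references (t_RV, t_lungs, t_LV in seconds), the LV reference AUC, and
#' QC flags raised during segmentation.
#'
#' @slot lavMl,ravMl atrial volumes (mL).
#' @slot laviMlM2,raviMlM2 BSA-indexed volumes (mL/m^2), NA if no BSA.
#' @slot bsaM2 body surface area (m^2), NA when height/weight not given.
#' @slot tLv,tRv,tLungs timing references (s).
#' @slot aucLv LV-cavity reference AUC (kBq.s/mL).
#' @slot flags character vector of QC flags (empty when clean).
#' @export
setClass("VolumeReport",
  representation(
    lavMl = "numeric", ravMl = "numeric",
    laviMlM2 = "numeric", raviMlM2 = "numeric", bsaM2 = "numeric",
    tLv = "numeric", tRv = "numeric", tLungs = "numeric",
    aucLv = "numeric", flags = "character"
  )
)

setValidity("VolumeReport", function(object) {
  msg <- NULL
  if (object@lavMl < 0 || object@ravMl < 0)
    msg <- c(msg, "volumes must be non-negative")
  if (is.null(msg)) TRUE else msg
})
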