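# Arterial and venous input functions by cluster analysis of voxel TACs.

# Deterministic, order-independent k-means++ seeding: candidates are put
# in a canonical order (by AUC, then t_mid, then peak value) before the
# seeded sampling, so permuting voxel order cannot change the result.
kmeansPlusPlusInit <- function(X, k, seed, key) {
  ord <- do.call(order, as.data.frame(key))
  Xo <- X[ord, , drop = FALSE]
  n <- nrow(Xo)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  centers <- matrix(0, k, ncol(Xo))
  ci <- sample.int(n, 1)
  centers[1, ] <- Xo[ci, ]
  d2 <- rowSums((Xo - matrix(centers[1, ], n, ncol(Xo), byrow = TRUE))^2)
  for (j in 2:k) {
    p <- d2 / sum(d2)
    ci <- sample.int(n, 1, prob = p)
    centers[j, ] <- Xo[ci, ]
    nd <- rowSums((Xo - matrix(centers[j, ], n, ncol(Xo), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  centers
}

#' Cluster analysis of voxel time-activity curves
#'
#' Derives the arterial (C_A) and venous (C_RV) whole-blood input
#' functions by k-means clustering (default 6 clusters) of
#' amplitude-normalized TACs. Candidate voxels are the peak-detected
#' voxels whose raw first-pass AUC exceeds the 75th percentile (a
#' pre-normalization bootstrap, since the LV reference is not yet known).
#' Cluster arrival times are measured by the first-pass centroid of the
#' cluster-mean TAC (robust to the coarse early frame durations). The
#' venous cluster is the earliest high-AUC cluster (mean AUC at least
#' `high_auc_frac` of the highest cluster). The arterial cluster is found
#' among high-AUC clusters arriving at least `min_av_lag_s` after the
#' venous one: the LV cavity and aorta are the last high-blood-volume
#' stations of the first pass, so candidates within `art_window_s` of the
#' latest arrival are kept and the highest-AUC one of those is selected.
#' The returned input functions are the mean raw TACs of the member
#' voxels.
#'
#' @param series a [DynamicSeries-class].
#' @param maps the [ParametricMaps-class] of the series (raw AUC is used).
#' @param k number of clusters (>= 3).
#' @param seed integer seed for the k-means++ initialization.
#' @param auc_quantile candidate-selection AUC quantile.
#' @param min_av_lag_s minimum arterial-after-venous peak lag (s).
#' @param high_auc_frac clusters with mean AUC at least this fraction of
#'   the highest cluster AUC count as high-AUC (blood clusters).
#' @param art_window_s arterial candidates must arrive within this window
#'   of the latest high-AUC lagged cluster (s).
#' @return an [InputFunctions-class] object.
#' @export
clusterInputFunctions <- function(series, maps, k = 6L, seed = 1L,
                                  auc_quantile = 0.75, min_av_lag_s = 4,
                                  high_auc_frac = 2 / 3,
                                  art_window_s = 2) {
  if (k < 3) stop("at least 3 clusters are required")
  d <- dim(seriesData(series))[1:3]
  nf <- nFrames(series)
  mid <- frameMid(series)
  det <- which(maps@detected)
  if (length(det) < 10 * k)
    stop("segmentation failure: too few peak-detected voxels for clustering")
  thr <- quantile(maps@auc[det], auc_quantile, na.rm = TRUE)
  cand <- det[maps@auc[det] > thr]
  flat <- matrix(seriesData(series), prod(d), nf)
  Y <- flat[cand, , drop = FALSE]
  amp <- pmax(apply(Y, 1, max), 1e-9)
  X <- Y / amp
  key <- cbind(maps@auc[cand], maps@tmid[cand], amp)
  centers <- kmeansPlusPlusInit(X, k, seed, key)
  km <- suppressWarnings(
    kmeans(X, centers = centers, iter.max = 100L, algorithm = "Lloyd"))
  lab <- km$cluster

  meanTacs <- matrix(0, k, nf)
  aucMean <- numeric(k)
  size <- numeric(k)
  for (j in seq_len(k)) {
    mj <- lab == j
    size[j] <- sum(mj)
    if (size[j] > 0) {
      meanTacs[j, ] <- colMeans(Y[mj, , drop = FALSE])
      aucMean[j] <- mean(maps@auc[cand[mj]])
    }
  }
  # cluster timing by first-pass centroid (robust to the coarse early
  # frames, unlike the argmax frame mid-time)
  sch <- data.frame(start = frameStart(series),
                    duration = frameDuration(series))
  peakT <- vapply(seq_len(k), function(j) {
    ct <- tacCentroid(meanTacs[j, ], sch)
    if (is.na(ct)) mid[which.max(meanTacs[j, ])] else ct
  }, numeric(1))
  highAUC <- which(aucMean >= high_auc_frac * max(aucMean) & size > 0)
  ven <- highAUC[which.min(peakT[highAUC])]
  art_cand <- which(peakT >= peakT[ven] + min_av_lag_s & size > 0)
  if (length(art_cand) == 0)
    stop("segmentation failure: no cluster satisfies the arterial lag ",
         "criterion (venous peak at ", round(peakT[ven], 1), " s, lag >= ",
         min_av_lag_s, " s required; cluster peaks at ",
         paste(round(peakT, 1), collapse = ", "), " s)")
  # the arterial pool (LV cavity / aorta) is the latest high-blood-volume
  # station of the first pass. Among high-AUC lagged clusters, restrict to
  # those arriving within art_window_s of the latest (separating LV/aorta
  # from the earlier LA) and take the highest-AUC one (preferring the LV
  # cluster over the smaller aorta cluster).
  art_high <- intersect(art_cand, highAUC)
  art <- if (length(art_high)) {
    win <- art_high[peakT[art_high] >= max(peakT[art_high]) - art_window_s]
    win[which.max(aucMean[win])]
  } else art_cand[which.max(aucMean[art_cand])]

  labArr <- array(NA_integer_, d)
  labArr[cand] <- lab
  new("InputFunctions",
      ca = pmax(meanTacs[art, ], 0), crv = pmax(meanTacs[ven, ], 0),
      frameMid = mid,
      clusterLabels = labArr, clusterMeans = meanTacs,
      clusterAUC = aucMean, clusterSize = size,
      arterialCluster = as.integer(art), venousCluster = as.integer(ven))
}

# First-pass centroid of one cluster-mean TAC (NA if no peak found).
tacCentroid <- function(tac, schedule, ...) {
  p <- extractFirstPassPeak(tac, schedule, ...)
  if (is.null(p)) return(NA_real_)
  unname(peakMetrics(p)["t_mid"])
}

#' Estimate the lung bolus-transit reference time
#'
#' The lung cluster is the cluster with intermediate normalized AUC
#' (between `auc_lo` and `auc_hi`) whose mean-TAC first-pass centroid lies
#' strictly between the venous and arterial centroids; among several such
#' clusters the most populous wins. `t_lungs` is the centroid time of that
#' cluster's mean TAC. When no cluster qualifies the midpoint of the
#' venous and arterial centroids is returned with a warning (fallback).
#'
#' @param inputs an [InputFunctions-class].
#' @param maps a normalized [ParametricMaps-class] (supplies the LV
#'   reference AUC used to express cluster AUCs on the normalized scale).
#' @param schedule frame schedule data.frame.
#' @param auc_lo,auc_hi normalized AUC band for lung candidates.
#' @return list with `t_lungs` (s) and `fallback` (logical).
#' @export
estimateLungTmid <- function(inputs, maps, schedule,
                             auc_lo = 0.15, auc_hi = 0.5) {
  if (is.null(maps@aucNorm))
    stop("AUC must be normalized before estimating the lung reference")
  tV <- tacCentroid(inputs@crv, schedule)
  tA <- tacCentroid(inputs@ca, schedule)
  aucN <- inputs@clusterAUC / maps@aucReference
  cent <- vapply(seq_len(nrow(inputs@clusterMeans)), function(j)
    tacCentroid(inputs@clusterMeans[j, ], schedule), numeric(1))
  ok <- which(aucN > auc_lo & aucN < auc_hi &
                !is.na(cent) & cent > tV & cent < tA)
  if (length(ok) == 0) {
    warning("no lung-like cluster found; using the venous/arterial midpoint")
    return(list(t_lungs = (tV + tA) / 2, fallback = TRUE))
  }
  j <- ok[which.max(inputs@clusterSize[ok])]
  list(t_lungs = cent[j], fallback = FALSE)
}
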