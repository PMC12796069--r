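# Voxel-wise first-pass indicator-dilution analysis: extract the bolus
# peak of every time-activity curve, compute its centroid time t_mid and
# area under the curve, and derive the blood mask.

#' First-pass peak extraction from a single TAC
#'
#' Locates the global maximum within the search window (default first
#' 120 s) and extends the segment left and right from the maximum until
#' the value falls below `tail_frac` of the peak, until a local minimum
#' below `recirc_frac` of the peak is reached (recirculation cut), or the
#' window ends. Returns `NULL` when the maximum is below the detection
#' threshold `max(min_peak_frac * background, min_peak_abs)`, where
#' `background` is the mean activity over the final third of the scan.
#'
#' @param tac frame TAC (kBq/mL).
#' @param schedule frame schedule data.frame (`start`, `duration` in s).
#' @param window_s search window (s).
#' @param tail_frac tail cutoff as a fraction of the peak.
#' @param recirc_frac local-minimum (recirculation) cutoff fraction.
#' @param min_peak_frac detection threshold in multiples of the late-frame
#'   background level.
#' @param min_peak_abs absolute detection floor (kBq/mL).
#' @return a list of class `FirstPassPeak` with elements `frames` (indices
#'   of the contiguous peak segment), `values`, `mid_s`, `duration_s`;
#'   or NULL when no peak is detected.
#' @examples
#' sch <- data.frame(start = 0:9, duration = rep(1, 10))
#' tac <- c(0, 1, 4, 9, 4, 1, 0, 0, 0, 0)
#' p <- extractFirstPassPeak(tac, sch)
#' peakMetrics(p)
#' @export
extractFirstPassPeak <- function(tac, schedule, window_s = 120,
                                 tail_frac = 0.10, recirc_frac = 0.5,
                                 min_peak_frac = 5, min_peak_abs = 0.5) {
  validateSchedule(schedule)
  nf <- nrow(schedule)
  if (length(tac) != nf) stop("tac length must equal the number of frames")
  mid <- schedule$start + schedule$duration / 2
  wlast <- max(which(mid <= window_s))
  i0 <- which.max(tac[seq_len(wlast)])
  peak <- tac[i0]
  lateIdx <- which(schedule$start >= 2 / 3 * sum(schedule$duration))
  bg <- if (length(lateIdx)) mean(abs(tac[lateIdx])) else 0
  if (peak < max(min_peak_frac * bg, min_peak_abs)) return(NULL)
  L <- i0
  while (L > 1) {
    prev <- tac[L - 1]
    if (prev < tail_frac * peak) break
    if (prev > tac[L] && tac[L] < recirc_frac * peak) break
    L <- L - 1
  }
  R <- i0
  while (R < wlast) {
    nxt <- tac[R + 1]
    if (nxt < tail_frac * peak) break
    if (nxt > tac[R] && tac[R] < recirc_frac * peak) break
    R <- R + 1
  }
  structure(list(frames = L:R, values = tac[L:R], mid_s = mid[L:R],
                 duration_s = schedule$duration[L:R]),
            class = "FirstPassPeak")
}

#' Centroid time and area of a first-pass peak
#'
#' The centroid time is the duration-weighted first moment of the peak
#' segment, \eqn{t_{mid} = \sum t_i C_i \Delta_i / \sum C_i \Delta_i} with
#' \eqn{t_i} the frame mid-times, and the area under the curve is
#' \eqn{AUC = \sum C_i \Delta_i}.
#'
#' @param peak a `FirstPassPeak` from [extractFirstPassPeak()].
#' @return named numeric with `t_mid` (s) and `auc` (kBq.s/mL).
#' @export
peakMetrics <- function(peak) {
  stopifnot(inherits(peak, "FirstPassPeak"))
  wsum <- sum(peak$values * peak$duration_s)
  if (wsum <= 0) stop("undefined centroid: peak segment has no positive area")
  c(t_mid = sum(peak$mid_s * peak$values * peak$duration_s) / wsum,
    auc = wsum)
}

# Vectorized peak extraction over a matrix of TACs (rows = voxels).
# Equivalent to extractFirstPassPeak()/peakMetrics() per row (tested).
extractPeaksMatrix <- function(V, schedule, window_s = 120,
                               tail_frac = 0.10, recirc_frac = 0.5,
                               min_peak_frac = 5, min_peak_abs = 0.5) {
  nv <- nrow(V)
  nf <- ncol(V)
  mid <- schedule$start + schedule$duration / 2
  dur <- schedule$duration
  wlast <- max(which(mid <= window_s))
  W <- V[, seq_len(wlast), drop = FALSE]
  i0 <- max.col(W, ties.method = "first")
  peak <- W[cbind(seq_len(nv), i0)]
  lateIdx <- which(schedule$start >= 2 / 3 * sum(dur))
  bg <- if (length(lateIdx))
    rowMeans(abs(V[, lateIdx, drop = FALSE])) else numeric(nv)
  detected <- peak >= pmax(min_peak_frac * bg, min_peak_abs)

  extend <- function(edge, dir) {
    active <- detected
    repeat {
      nxtIdx <- edge + dir
      can <- active & nxtIdx >= 1 & nxtIdx <= wlast
      if (!any(can)) break
      iv <- which(can)
      nxt <- V[cbind(iv, nxtIdx[iv])]
      cur <- V[cbind(iv, edge[iv])]
      stop_tail <- nxt < tail_frac * peak[iv]
      stop_min <- nxt > cur & cur < recirc_frac * peak[iv]
      ok <- !(stop_tail | stop_min)
      edge[iv[ok]] <- edge[iv[ok]] + dir
      active[] <- FALSE
      active[iv[ok]] <- TRUE
      if (!any(ok)) break
    }
    edge
  }
  L <- extend(i0, -1L)
  R <- extend(i0, +1L)

  tmid <- rep(NA_real_, nv)
  auc <- rep(NA_real_, nv)
  idx <- which(detected)
  if (length(idx)) {
    # accumulate sums over the per-voxel segments frame by frame
    s0 <- numeric(length(idx))
    s1 <- numeric(length(idx))
    for (f in seq_len(wlast)) {
      inseg <- L[idx] <= f & R[idx] >= f
      if (!any(inseg)) next
      v <- V[idx[inseg], f] * dur[f]
      s0[inseg] <- s0[inseg] + v
      s1[inseg] <- s1[inseg] + v * mid[f]
    }
    pos <- s0 > 0
    tmid[idx[pos]] <- s1[pos] / s0[pos]
    auc[idx[pos]] <- s0[pos]
    detected[idx[!pos]] <- FALSE
  }
  list(tmid = tmid, auc = auc, detected = detected, L = L, R = R)
}

#' Compute parametric t_mid and AUC images
#'
#' Applies first-pass peak extraction and centroid/area computation to
#' every voxel of a dynamic series, producing a 3D image of bolus centroid
#' time t_mid and of first-pass AUC. Voxels without a detectable peak are
#' flagged (NA in both maps). AUC normalization is deferred until the
#' LV-cavity reference is known (see [normalizeAUC()]).
#'
#' @param series a [DynamicSeries-class].
#' @param ... peak-extraction parameters passed to the extractor
#'   (see [extractFirstPassPeak()]).
#' @return a [ParametricMaps-class] object.
#' @export
computeParametricMaps <- function(series, ...) {
  d <- dim(seriesData(series))[1:3]
  nf <- nFrames(series)
  sch <- data.frame(start = frameStart(series),
                    duration = frameDuration(series))
  flat <- matrix(seriesData(series), prod(d), nf)
  res <- extractPeaksMatrix(flat, sch, ...)
  new("ParametricMaps",
      tmid = array(res$tmid, d), auc = array(res$auc, d),
      detected = array(res$detected, d), aucNorm = NULL,
      aucReference = NA_real_, spacing = voxelSpacing(series))
}

#' Normalize the AUC image to the LV-cavity reference
#'
#' AUC is normalized such that the LV blood pool has a normalized area
#' of 1: `aucNorm = auc / auc_lv_reference`.
#'
#' @param maps a [ParametricMaps-class].
#' @param auc_lv_reference AUC of the LV-cavity TAC (kBq.s/mL), > 0.
#' @return the maps with `aucNorm` and `aucReference` filled in.
#' @export
normalizeAUC <- function(maps, auc_lv_reference) {
  stopifnot(is(maps, "ParametricMaps"), auc_lv_reference > 0)
  maps@aucNorm <- maps@auc / auc_lv_reference
  maps@aucReference <- auc_lv_reference
  validObject(maps)
  maps
}

#' Blood-region mask from the parametric maps
#'
#' The blood region is every peak-detected voxel with normalized AUC above
#' 2/3 of the LV cavity and a short bolus centroid time (below 1.5 min):
#' `aucNorm > auc_frac & tmid < tmid_max_s`.
#'
#' @param maps a normalized [ParametricMaps-class].
#' @param auc_frac AUC threshold as a fraction of the LV blood pool (2/3).
#' @param tmid_max_s centroid-time threshold (90 s).
#' @return logical 3D array.
#' @export
bloodMask <- function(maps, auc_frac = 2 / 3, tmid_max_s = 90) {
  if (is.null(maps@aucNorm))
    stop("AUC has not been normalized yet; call normalizeAUC() first")
  m <- maps@detected & !is.na(maps@aucNorm) & maps@aucNorm > auc_frac &
    maps@tmid < tmid_max_s
  m[is.na(m)] <- FALSE
  m
}
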