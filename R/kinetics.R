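# Single-tissue compartment model for O-15 water:
#   C_T(t) = PTF * MBF * C_A(t) (x) exp(-MBF/V_T * t)
#            + V_A * C_A(t) + V_RV * C_RV(t)
# with the distribution volume V_T fixed to 0.91 mL/g. MBF is reported in
# mL/g/min; inside the exponent and the flow term it is converted to per
# second (MBF / 60).

#' Kinetic model configuration
#'
#' @param v_t fixed water distribution volume (mL/g), 0.91.
#' @param mbf_grid basis grid of MBF values (mL/g/min); default 100
#'   log-spaced points in \[0.1, 5\].
#' @param fine_dt convolution grid step (s).
#' @param nonneg constrain all coefficients to be non-negative.
#' @return list of class `KineticModelConfig`.
#' @export
kineticModelConfig <- function(v_t = 0.91,
                               mbf_grid = logspace(0.1, 5.0, 100),
                               fine_dt = 1.0, nonneg = TRUE) {
  stopifnot(v_t > 0, all(diff(mbf_grid) > 0), fine_dt > 0)
  structure(list(v_t = v_t, mbf_grid = mbf_grid, fine_dt = fine_dt,
                 nonneg = nonneg),
            class = "KineticModelConfig")
}

# Trapezoidal convolution of sampled input c with exp(-k2 t) on a uniform
# grid of step dt: b[n] = int_0^{t_n} c(tau) exp(-k2 (t_n - tau)) dtau.
convolveExp <- function(c, dt, k2) {
  n <- length(c)
  b <- numeric(n)
  E <- exp(-k2 * dt)
  for (i in 2:n) b[i] <- E * b[i - 1] + dt / 2 * (c[i] + E * c[i - 1])
  b
}

# Trapezoidal frame averages of a curve sampled on a uniform fine grid
# starting at t = 0.
frameAverageGrid <- function(vals, tFine, schedule) {
  dt <- tFine[2] - tFine[1]
  vapply(seq_len(nrow(schedule)), function(f) {
    a <- schedule$start[f]
    b <- a + schedule$duration[f]
    i0 <- which.min(abs(tFine - a))
    i1 <- which.min(abs(tFine - b))
    v <- vals[i0:i1]
    (sum(v) - (v[1] + v[length(v)]) / 2) * dt / (b - a)
  }, numeric(1))
}

# Linear interpolation of a frame TAC onto a fine grid; the curve is
# anchored at (0, 0) before the first frame mid-time.
tacToFine <- function(tac, frameMid, tFine) {
  stats::approx(c(0, frameMid), c(0, tac), xout = tFine, rule = 2)$y
}

#' Simulate a tissue time-activity curve
#'
#' Forward single-tissue compartment model: the flow term is computed by
#' trapezoidal convolution on a fine time grid and then frame-averaged; the
#' blood terms `v_a * C_A` and `v_rv * C_RV` are added at the frame level so
#' that e.g. `mbf = 0` returns exactly `v_a * C_A + v_rv * C_RV`.
#'
#' @param mbf myocardial blood flow (mL/g/min), >= 0.
#' @param ptf perfusable tissue fraction (g/mL), >= 0.
#' @param v_a,v_rv arterial and right-ventricular blood volume fractions.
#' @param ca,crv input functions: frame TACs (kBq/mL) when `input_time` is
#'   NULL, otherwise samples on the uniform fine grid `input_time`.
#' @param schedule frame schedule data.frame (`start`, `duration`).
#' @param v_t distribution volume (mL/g).
#' @param fine_dt convolution step (s) when inputs are frame TACs.
#' @param input_time optional fine grid (s) on which `ca`/`crv` are sampled.
#' @return frame TAC of the modeled tissue voxel (kBq/mL).
#' @export
simulateTissueTac <- function(mbf, ptf, v_a, v_rv, ca, crv, schedule,
                              v_t = 0.91, fine_dt = 1.0,
                              input_time = NULL) {
  stopifnot(mbf >= 0, ptf >= 0, v_a >= 0, v_rv >= 0, v_t > 0)
  validateSchedule(schedule)
  nf <- nrow(schedule)
  tEnd <- schedule$start[nf] + schedule$duration[nf]
  mid <- schedule$start + schedule$duration / 2
  if (is.null(input_time)) {
    tFine <- seq(0, tEnd, by = fine_dt)
    caFine <- tacToFine(ca, mid, tFine)
    caFrames <- ca
    crvFrames <- crv
  } else {
    tFine <- input_time
    caFine <- ca
    caFrames <- frameAverageGrid(ca, tFine, schedule)
    crvFrames <- frameAverageGrid(crv, tFine, schedule)
  }
  flow <- if (mbf > 0 && ptf > 0) {
    k2 <- mbf / 60 / v_t
    conv <- convolveExp(caFine, tFine[2] - tFine[1], k2)
    frameAverageGrid(ptf * (mbf / 60) * conv, tFine, schedule)
  } else rep(0, nf)
  flow + v_a * caFrames + v_rv * crvFrames
}

# Precompute the frame-averaged basis set for the MBF grid.
# Basis i already carries the PTF-free flow scaling MBF_i/60, so the
# fitted coefficients are (PTF, V_A, V_RV) directly.
basisSet <- function(inputs, schedule, cfg) {
  nf <- nrow(schedule)
  tEnd <- schedule$start[nf] + schedule$duration[nf]
  mid <- schedule$start + schedule$duration / 2
  tFine <- seq(0, tEnd, by = cfg$fine_dt)
  caFine <- tacToFine(inputs@ca, mid, tFine)
  ng <- length(cfg$mbf_grid)
  B <- matrix(0, nf, ng)
  for (i in seq_len(ng)) {
    k2 <- cfg$mbf_grid[i] / 60 / cfg$v_t
    conv <- convolveExp(caFine, cfg$fine_dt, k2)
    B[, i] <- frameAverageGrid((cfg$mbf_grid[i] / 60) * conv, tFine,
                               schedule)
  }
  list(B = B, caF = inputs@ca, crvF = inputs@crv,
       mbf_grid = cfg$mbf_grid)
}

# Exact non-negative weighted least squares for a 3-column design by
# enumeration of coefficient supports (the global NNLS optimum for 3
# variables is the best feasible support solution).
nnls3 <- function(G, b, yWy, coefU, rssU) {
  nv <- ncol(coefU)
  best_rss <- yWy # empty support: all coefficients zero
  best_coef <- matrix(0, 3, nv)
  viol <- which(colSums(coefU < -1e-12) > 0)
  keep <- setdiff(seq_len(nv), viol)
  best_rss[keep] <- rssU[keep]
  best_coef[, keep] <- coefU[, keep]
  if (length(viol) == 0)
    return(list(coef = best_coef, rss = best_rss))
  subsets <- list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L))
  for (S in subsets) {
    GS <- G[S, S, drop = FALSE]
    cS <- tryCatch(solve(GS, b[S, viol, drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(cS)) next
    cS <- matrix(cS, length(S), length(viol))
    feas <- colSums(cS < -1e-12) == 0
    if (!any(feas)) next
    cf <- matrix(0, 3, length(viol))
    cf[S, ] <- cS
    cross <- colSums(cf * b[, viol, drop = FALSE])
    quad <- colSums(cf * (G %*% cf))
    rss <- yWy[viol] - 2 * cross + quad
    upd <- feas & rss < best_rss[viol] - 1e-12
    if (any(upd)) {
      vi <- viol[upd]
      best_rss[vi] <- rss[upd]
      best_coef[, vi] <- cf[, upd]
    }
  }
  list(coef = best_coef, rss = best_rss)
}

# Vectorized basis-function fit. Y: nf x nvox matrix of TACs.
# Returns 5 x nvox matrix (mbf, ptf, va, vrv, rss).
fitVoxelsMatrix <- function(Y, basis, schedule, cfg) {
  nf <- nrow(Y)
  w <- schedule$duration / sum(schedule$duration)
  nv <- ncol(Y)
  yWy <- colSums(Y * Y * w)
  best <- matrix(NA_real_, 5, nv)
  best_rss <- rep(Inf, nv)
  for (i in seq_along(basis$mbf_grid)) {
    A <- cbind(basis$B[, i], basis$caF, basis$crvF)
    Aw <- A * w
    G <- crossprod(A, Aw)
    b <- crossprod(Aw, Y)
    coefU <- tryCatch(solve(G, b), error = function(e) NULL)
    if (is.null(coefU)) next
    cross <- colSums(coefU * b)
    quad <- colSums(coefU * (G %*% coefU))
    rssU <- yWy - 2 * cross + quad
    if (cfg$nonneg) {
      r <- nnls3(G, b, yWy, coefU, rssU)
      coef <- r$coef
      rss <- r$rss
    } else {
      coef <- coefU
      rss <- rssU
    }
    upd <- rss < best_rss - 1e-15 # ties keep the smaller MBF
    if (any(upd)) {
      best_rss[upd] <- rss[upd]
      best[1, upd] <- basis$mbf_grid[i]
      best[2, upd] <- coef[1, upd]
      best[3, upd] <- coef[2, upd]
      best[4, upd] <- coef[3, upd]
      best[5, upd] <- rss[upd]
    }
  }
  # all-zero TACs: flagged null fit
  null <- colSums(abs(Y)) == 0
  best[, null] <- NA_real_
  best
}

#' Fit the kinetic model in a single voxel
#'
#' Basis-function fit: for every MBF value on the grid the model is linear
#' in (PTF, V_A, V_RV); a weighted (non-negative) least-squares solve per
#' basis function and a search over the grid give the global fit. Frame
#' weights are proportional to frame duration. Ties on the residual grid
#' keep the smallest MBF.
#'
#' @param tac frame TAC of the voxel (kBq/mL).
#' @param inputs an [InputFunctions-class] object.
#' @param schedule frame schedule data.frame.
#' @param cfg a [kineticModelConfig()].
#' @return named numeric: mbf, ptf, va, vrv, rss (NA for an all-zero TAC).
#' @export
fitSingleVoxel <- function(tac, inputs, schedule, cfg = kineticModelConfig()) {
  if (length(tac) != nrow(schedule))
    stop("tac length must equal the number of frames")
  basis <- basisSet(inputs, schedule, cfg)
  r <- fitVoxelsMatrix(matrix(tac, ncol = 1), basis, schedule, cfg)
  c(mbf = r[1, 1], ptf = r[2, 1], va = r[3, 1], vrv = r[4, 1],
    rss = r[5, 1])
}

#' Fit kinetic parametric maps
#'
#' Applies the basis-function single-tissue model voxel-wise over a mask
#' (by default every peak-detected voxel), sharing one precomputed basis
#' set, and returns MBF, PTF, V_A, V_RV and residual images.
#'
#' @param series a [DynamicSeries-class].
#' @param inputs an [InputFunctions-class].
#' @param cfg a [kineticModelConfig()].
#' @param mask logical 3D array of voxels to fit.
#' @return a [KineticMaps-class] object.
#' @export
fitParametricMaps <- function(series, inputs, cfg = kineticModelConfig(),
                              mask) {
  d <- dim(seriesData(series))[1:3]
  stopifnot(identical(dim(mask), d))
  sch <- data.frame(start = frameStart(series),
                    duration = frameDuration(series))
  basis <- basisSet(inputs, sch, cfg)
  idx <- which(mask)
  nf <- nFrames(series)
  mk <- function() array(NA_real_, d)
  maps <- list(mbf = mk(), ptf = mk(), va = mk(), vrv = mk(), rss = mk())
  if (length(idx) > 0) {
    flat <- matrix(seriesData(series), prod(d), nf)
    chunk <- 50000L
    for (s in seq(1, length(idx), by = chunk)) {
      ii <- idx[s:min(s + chunk - 1L, length(idx))]
      r <- fitVoxelsMatrix(t(flat[ii, , drop = FALSE]), basis, sch, cfg)
      maps$mbf[ii] <- r[1, ]
      maps$ptf[ii] <- r[2, ]
      maps$va[ii] <- r[3, ]
      maps$vrv[ii] <- r[4, ]
      maps$rss[ii] <- r[5, ]
    }
  }
  new("KineticMaps", mbf = maps$mbf, ptf = maps$ptf, va = maps$va,
      vrv = maps$vrv, rss = maps$rss, fitted = mask,
      spacing = voxelSpacing(series))
}
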