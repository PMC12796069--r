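# Synthetic dynamic cardiac PET phantom: known chamber geometry, bolus
# timing and tissue kinetics, used as ground truth for the whole pipeline.

#' Default dynamic frame schedule
#'
#' The clinical 6-minute dynamic acquisition: 22 frames
#' (1 x 10 s, 8 x 5 s, 4 x 10 s, 2 x 15 s, 3 x 20 s, 2 x 30 s, 2 x 60 s).
#'
#' @return data.frame with columns `start` and `duration` (seconds).
#' @examples
#' sch <- defaultFrameSchedule()
#' nrow(sch)                 # 22 frames
#' sum(sch$duration)         # 360 s
#' @export
defaultFrameSchedule <- function() {
  dur <- c(10, rep(5, 8), rep(10, 4), rep(15, 2), rep(20, 3),
           rep(30, 2), rep(60, 2))
  data.frame(start = cumsum(c(0, dur[-length(dur)])), duration = dur)
}

#' Gamma-variate bolus curve
#'
#' First-pass bolus model
#' \deqn{C(t) = A \left(\frac{t - t_0}{\alpha\beta}\right)^{\alpha}
#'   e^{\alpha - (t - t_0)/\beta}} for \eqn{t \ge t_0}, 0 before arrival.
#' The curve peaks at \eqn{t_0 + \alpha\beta} with value A, and its
#' centroid (first moment) is at \eqn{t_0 + \beta(\alpha + 1)} — the
#' closed form used to validate centroid-time estimation.
#'
#' @param t time (s), vectorized.
#' @param t0 bolus arrival delay (s).
#' @param alpha shape parameter (> 0, unitless).
#' @param beta scale parameter (> 0, s).
#' @param amplitude peak activity (kBq/mL).
#' @return activity values (kBq/mL), non-negative.
#' @examples
#' t <- seq(0, 60, 0.5)
#' c1 <- bolusCurve(t, t0 = 10, alpha = 3, beta = 1.5, amplitude = 100)
#' @export
bolusCurve <- function(t, t0, alpha, beta, amplitude) {
  if (alpha <= 0 || beta <= 0)
    stop("bolus parameters alpha and beta must be positive")
  dt <- t - t0
  out <- numeric(length(t))
  ok <- dt > 0
  out[ok] <- amplitude * (dt[ok] / (alpha * beta))^alpha *
    exp(alpha - dt[ok] / beta)
  out
}

# Analytic centroid of the gamma-variate bolus.
bolusCentroid <- function(t0, alpha, beta) t0 + beta * (alpha + 1)

# Full structure curve: main bolus plus a delayed, dispersed recirculation
# copy (default 15% amplitude, +30 s, doubled scale).
structureCurve <- function(t, p, recirc) {
  main <- bolusCurve(t, p$t0, p$alpha, p$beta, p$amplitude)
  if (is.null(recirc) || recirc$amp_frac <= 0) return(main)
  main + bolusCurve(t, p$t0 + recirc$delay_s, p$alpha,
                    p$beta * recirc$beta_mult,
                    p$amplitude * recirc$amp_frac)
}

#' Average a continuous activity curve over a frame schedule
#'
#' Each frame value is the mean of the curve over the half-open interval
#' \[start, start + duration), computed by adaptive quadrature.
#'
#' @param curve vectorized function of time (s).
#' @param schedule data.frame with `start`, `duration` columns (s).
#' @return numeric vector of frame means.
#' @examples
#' frameAverage(function(t) 2 * t, defaultFrameSchedule())
#' @export
frameAverage <- function(curve, schedule) {
  validateSchedule(schedule)
  vapply(seq_len(nrow(schedule)), function(i) {
    a <- schedule$start[i]
    b <- a + schedule$duration[i]
    stats::integrate(curve, a, b, rel.tol = 1e-8,
                     subdivisions = 400L)$value / (b - a)
  }, numeric(1))
}

validateSchedule <- function(schedule) {
  if (!all(c("start", "duration") %in% names(schedule)))
    stop("schedule needs 'start' and 'duration' columns")
  if (any(schedule$duration <= 0)) stop("frame durations must be positive")
  n <- nrow(schedule)
  if (n > 1) {
    gap <- schedule$start[-1] -
      (schedule$start[-n] + schedule$duration[-n])
    if (any(gap < -1e-9)) stop("overlapping frames in schedule")
    if (any(abs(gap) > 1e-6)) stop("schedule must be contiguous")
  }
  invisible(schedule)
}

#' Phantom specification
#'
#' Builds the full specification of the synthetic cardiac phantom: grid and
#' voxel size, analytic chamber geometry (ellipsoids, myocardial shells,
#' cylinders for aorta and SVC, paired lung ellipsoids), gamma-variate
#' bolus parameters per structure with the physiological transit ordering
#' SVC -> RA -> RV -> lungs -> LA -> LV -> aorta, tissue kinetic parameters
#' for both myocardial walls, point-spread-function width, and the noise
#' level. The default geometry fills a 192 mm field of view; other fields
#' of view scale the geometry isotropically.
#'
#' @param grid_shape voxels per axis.
#' @param voxel_size mm per axis (scalar or length 3).
#' @param la_radius,ra_radius atrial radii (mm, at the 192 mm reference
#'   field of view).
#' @param rotation_deg rotation of the whole phantom about the y axis
#'   (degrees); exercises the short-axis reorientation.
#' @param psf_fwhm reconstructed resolution modeled as an isotropic
#'   Gaussian point-spread function (mm FWHM).
#' @param noise_scale unitless noise level (>= 0); the per-frame noise
#'   standard deviation is `noise_scale * sqrt(value / duration)`.
#' @param heart_rate heart rate (bpm), carried as ground-truth metadata.
#' @param rng_seed integer seed making generation bit-reproducible.
#' @param frame_schedule frame schedule data.frame (`start`, `duration`).
#' @return a list of class `PhantomSpec`.
#' @examples
#' spec <- phantomSpec(grid_shape = c(48, 48, 48), voxel_size = 4)
#' @export
phantomSpec <- function(grid_shape = c(96, 96, 96),
                        voxel_size = c(2, 2, 2),
                        la_radius = 26, ra_radius = 28,
                        rotation_deg = 0,
                        psf_fwhm = 5,
                        noise_scale = 1,
                        heart_rate = 60,
                        rng_seed = 42L,
                        frame_schedule = defaultFrameSchedule()) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8),
            all(voxel_size > 0), noise_scale >= 0, heart_rate > 0)
  validateSchedule(frame_schedule)
  s <- min(grid_shape * voxel_size) / 192 # 192 mm reference field of view
  ell <- function(center, semi) list(type = "ellipsoid",
                                     center = center * s, semi = semi * s)
  cyl <- function(center, radius, half_len, axis = c(0, 0, 1))
    list(type = "cylinder", center = center * s, radius = radius * s,
         half_len = half_len * s, axis = axis / sqrt(sum(axis^2)))
  geom <- list(
    lv_cavity = ell(c(120, 95, 90), c(20, 20, 40)),
    lv_myocardium = ell(c(120, 95, 90), c(30, 30, 50)), # shell outer surface
    rv_cavity = ell(c(58, 95, 90), c(18, 18, 35)),
    rv_myocardium = ell(c(58, 95, 90), c(24, 24, 41)),
    la = ell(c(120, 130, 155), rep(la_radius, 3)),
    ra = ell(c(58, 138, 138), rep(ra_radius, 3)),
    aorta = cyl(c(120, 65, 160), 12, 25),
    svc = cyl(c(58, 138, 175), 10, 14),
    lung_left = ell(c(20, 95, 110), c(17, 45, 60)),
    lung_right = ell(c(172, 95, 110), c(17, 45, 60))
  )
  bolus <- list(
    svc = list(t0 = 3, alpha = 3, beta = 1.5, amplitude = 100),
    ra = list(t0 = 4, alpha = 3, beta = 1.5, amplitude = 100),
    rv_cavity = list(t0 = 6, alpha = 3, beta = 1.5, amplitude = 100),
    lungs = list(t0 = 11, alpha = 3, beta = 1.5, amplitude = 30),
    la = list(t0 = 17, alpha = 3, beta = 1.5, amplitude = 100),
    lv_cavity = list(t0 = 20, alpha = 3, beta = 1.5, amplitude = 100),
    aorta = list(t0 = 21, alpha = 3, beta = 1.5, amplitude = 100)
  )
  tissue <- list(
    lv_myocardium = list(mbf = 0.9, ptf = 0.65, va = 0.15, vrv = 0.03),
    rv_myocardium = list(mbf = 0.9, ptf = 0.60, va = 0.05, vrv = 0.15)
  )
  spec <- list(
    grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
    geometry = geom, bolus = bolus, tissue = tissue,
    recirc = list(delay_s = 30, amp_frac = 0.15, beta_mult = 2),
    rotation_deg = rotation_deg, psf_fwhm = psf_fwhm,
    noise_scale = noise_scale, heart_rate = heart_rate,
    rng_seed = as.integer(rng_seed), frame_schedule = frame_schedule,
    fine_dt = 0.5
  )
  class(spec) <- "PhantomSpec"
  validatePhantomSpec(spec)
  spec
}

# Bolus delay ordering and geometry-extent invariants.
validatePhantomSpec <- function(spec) {
  b <- spec$bolus
  t0 <- function(s) b[[s]]$t0
  if (!(t0("rv_cavity") < t0("lungs") && t0("lungs") < t0("la") &&
        t0("la") < t0("lv_cavity") && t0("lv_cavity") <= t0("aorta")))
    stop("bolus delays must satisfy RV < lungs < LA < LV <= aorta")
  if (!(t0("ra") <= t0("rv_cavity") && t0("svc") <= t0("ra")))
    stop("bolus delays must satisfy SVC <= RA <= RV")
  for (p in b)
    if (p$alpha <= 0 || p$beta <= 0)
      stop("bolus alpha and beta must be positive")
  # structures must lie within the grid's physical box (they may overhang
  # the outermost voxel centres by up to one voxel; the voxelization
  # clips that sliver). This catches gross misplacement only.
  h <- spec$voxel_size
  for (nm in names(spec$geometry)) {
    g <- spec$geometry[[nm]]
    ext <- if (g$type == "ellipsoid") g$semi else
      abs(g$axis) * g$half_len + (1 - abs(g$axis)) * g$radius
    lo <- g$center - ext
    hi <- g$center + ext
    if (spec$rotation_deg == 0 &&
        (any(lo < -h - 1e-6) || any(hi > spec$grid_shape * h + 1e-6)))
      stop("structure '", nm, "' extends beyond the grid")
  }
  invisible(spec)
}

# Rotation matrix about the y axis (degrees).
rotY <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3)
}

# Voxelize all structures. Returns a list of disjoint logical masks, with
# assignment priority cavity > myocardium > atria > vessels > lungs.
voxelizeGeometry <- function(spec) {
  d <- spec$grid_shape
  cm <- voxelCoordsMm(d, spec$voxel_size)
  # rotate coordinates about the grid centre (inverse rotation of points)
  ctr <- (d - 1) * spec$voxel_size / 2
  R <- rotY(-spec$rotation_deg)
  P <- cbind(rep(cm$x, times = d[2] * d[3]) - ctr[1],
             rep(rep(cm$y, each = d[1]), times = d[3]) - ctr[2],
             rep(cm$z, each = d[1] * d[2]) - ctr[3])
  P <- P %*% t(R)
  P <- sweep(P, 2, -ctr) # back to world mm in the phantom's own frame
  inStructure <- function(g) {
    if (g$type == "ellipsoid") {
      q <- ((P[, 1] - g$center[1]) / g$semi[1])^2 +
        ((P[, 2] - g$center[2]) / g$semi[2])^2 +
        ((P[, 3] - g$center[3]) / g$semi[3])^2
      q <= 1
    } else {
      rel <- cbind(P[, 1] - g$center[1], P[, 2] - g$center[2],
                   P[, 3] - g$center[3])
      along <- rel %*% g$axis
      perp2 <- rowSums(rel^2) - along^2
      perp2 <= g$radius^2 & abs(along) <= g$half_len
    }
  }
  g <- spec$geometry
  raw <- list(
    lv_cavity = inStructure(g$lv_cavity),
    rv_cavity = inStructure(g$rv_cavity),
    lv_myocardium = inStructure(g$lv_myocardium),
    rv_myocardium = inStructure(g$rv_myocardium),
    la = inStructure(g$la),
    ra = inStructure(g$ra),
    aorta = inStructure(g$aorta),
    svc = inStructure(g$svc),
    lungs = inStructure(g$lung_left) | inStructure(g$lung_right)
  )
  # shells = outer ellipsoid minus own cavity
  raw$lv_myocardium <- raw$lv_myocardium & !raw$lv_cavity
  raw$rv_myocardium <- raw$rv_myocardium & !raw$rv_cavity
  taken <- rep(FALSE, nrow(P))
  masks <- list()
  for (nm in names(raw)) {
    m <- raw[[nm]] & !taken
    taken <- taken | m
    masks[[nm]] <- array(m, d)
  }
  masks
}

#' Generate a synthetic dynamic cardiac PET series
#'
#' Voxelizes the phantom geometry, assigns every blood structure its
#' frame-averaged gamma-variate bolus curve (with a recirculation tail),
#' drives myocardial voxels with the forward single-tissue compartment
#' model (arterial input = LV curve, venous spillover = RV curve), applies
#' an isotropic Gaussian point-spread function and finally heteroscedastic
#' Gaussian noise with per-frame standard deviation
#' `noise_scale * sqrt(value / duration)`. The same spec and seed always
#' produce bit-identical output.
#'
#' @param spec a [phantomSpec()] object.
#' @return list with elements `series` (a [DynamicSeries-class]) and
#'   `truth` (ground-truth masks, volumes in mL, analytic first-pass
#'   centroid times per structure, tissue parameters and the spec itself).
#' @examples
#' ph <- generatePhantom(phantomSpec(grid_shape = c(32, 32, 32),
#'                                   voxel_size = 6, noise_scale = 0))
#' ph$truth$volumes_ml["la"]
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  validatePhantomSpec(spec)
  masks <- voxelizeGeometry(spec)
  d <- spec$grid_shape
  sch <- spec$frame_schedule
  nf <- nrow(sch)
  vol <- array(0, c(d, nf))

  curveFor <- function(name) {
    p <- spec$bolus[[name]]
    function(t) structureCurve(t, p, spec$recirc)
  }
  bloodNames <- c("lv_cavity", "rv_cavity", "la", "ra", "aorta", "svc")
  tacs <- list()
  for (nm in bloodNames)
    tacs[[nm]] <- frameAverage(curveFor(nm), sch)
  tacs$lungs <- frameAverage(curveFor("lungs"), sch)

  # myocardium: forward kinetic model on a fine grid, LV curve as arterial
  # input and RV curve as venous spillover
  tEnd <- sch$start[nf] + sch$duration[nf]
  tFine <- seq(0, tEnd, by = spec$fine_dt)
  caFine <- curveFor("lv_cavity")(tFine)
  crvFine <- curveFor("rv_cavity")(tFine)
  for (nm in c("lv_myocardium", "rv_myocardium")) {
    tp <- spec$tissue[[nm]]
    tacs[[nm]] <- simulateTissueTac(tp$mbf, tp$ptf, tp$va, tp$vrv,
                                    ca = caFine, crv = crvFine,
                                    schedule = sch, v_t = 0.91,
                                    input_time = tFine)
  }

  for (nm in names(tacs)) {
    m <- masks[[nm]]
    if (!any(m)) next
    idx <- which(m)
    for (f in seq_len(nf))
      vol[idx + (f - 1) * prod(d)] <- tacs[[nm]][f]
  }

  if (spec$psf_fwhm > 0)
    for (f in seq_len(nf))
      vol[, , , f] <- gaussBlur3d(vol[, , , f], spec$psf_fwhm,
                                  spec$voxel_size)

  if (spec$noise_scale > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(spec$rng_seed)
    for (f in seq_len(nf)) {
      sdv <- spec$noise_scale * sqrt(pmax(vol[, , , f], 0) / sch$duration[f])
      vol[, , , f] <- vol[, , , f] + array(rnorm(prod(d)), d) * sdv
    }
  }

  series <- DynamicSeries(vol, spec$voxel_size, sch$start, sch$duration)
  voxMl <- prod(spec$voxel_size) / 1000
  volumes <- vapply(masks, function(m) sum(m) * voxMl, numeric(1))
  centroids <- vapply(names(spec$bolus), function(nm) {
    p <- spec$bolus[[nm]]
    bolusCentroid(p$t0, p$alpha, p$beta)
  }, numeric(1))
  list(series = series,
       truth = list(masks = masks, volumes_ml = volumes,
                    centroid_s = centroids, tissue = spec$tissue,
                    tacs = tacs, spec = spec))
}
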