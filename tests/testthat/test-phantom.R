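# Gamma-variate bolus model, frame averaging and phantom generation.

test_that("bolus curve obeys zero, linearity and positivity properties", {
  t <- seq(0, 120, 0.5)
  expect_equal(bolusCurve(t, 10, 3, 1.5, 0), rep(0, length(t)))
  c1 <- bolusCurve(t, 10, 3, 1.5, 50)
  c2 <- bolusCurve(t, 10, 3, 1.5, 100)
  expect_equal(c2, 2 * c1)
  expect_true(all(c1 >= 0))
  expect_true(all(bolusCurve(t[t < 10], 10, 3, 1.5, 50) == 0))
  expect_error(bolusCurve(t, 10, -1, 1.5, 50), "positive")
  expect_error(bolusCurve(t, 10, 3, 0, 50), "positive")
})

test_that("bolus centroid matches fine quadrature of the first moment", {
  # closed form t0 + beta * (alpha + 1) against a 0.01 s Riemann sum
  for (p in list(c(10, 3, 4), c(5, 2, 1.5), c(20, 4, 2.5))) {
    tg <- seq(0, 400, 0.01)
    cv <- bolusCurve(tg, p[1], p[2], p[3], 80)
    num <- sum(tg * cv) / sum(cv)
    expect_lt(abs(num - (p[1] + p[3] * (p[2] + 1))), 0.01)
  }
})

test_that("frame averaging is exact for constant and linear curves", {
  sch <- defaultFrameSchedule()
  expect_equal(frameAverage(function(t) rep(7, length(t)), sch),
               rep(7, 22))
  mid <- sch$start + sch$duration / 2
  expect_equal(frameAverage(function(t) 3 * t, sch), 3 * mid,
               tolerance = 1e-8)
})

test_that("frame averaging of a gamma-variate matches a midpoint-rule oracle", {
  sch <- defaultFrameSchedule()
  f <- function(t) bolusCurve(t, 12, 3, 2, 100)
  got <- frameAverage(f, sch)
  oracle <- vapply(seq_len(nrow(sch)), function(i) {
    tt <- seq(sch$start[i] + 5e-4, sch$start[i] + sch$duration[i] - 5e-4,
              by = 1e-3)
    mean(f(tt))
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-3)
})

test_that("invalid frame schedules are rejected", {
  bad <- data.frame(start = c(0, 4), duration = c(5, 5)) # overlap
  expect_error(frameAverage(function(t) t, bad), "overlap")
  gap <- data.frame(start = c(0, 6), duration = c(5, 5))
  expect_error(frameAverage(function(t) t, gap), "contiguous")
})

test_that("phantom spec enforces transit ordering and grid extents", {
  sp <- phantomSpec(grid_shape = c(64, 64, 64), voxel_size = 3)
  sp$bolus$la$t0 <- 25 # later than the LV: unphysiological
  expect_error(atriaPET:::validatePhantomSpec(sp), "LA < LV")
  sp2 <- phantomSpec(grid_shape = c(64, 64, 64), voxel_size = 3)
  sp2$geometry$la$center <- c(300, 95, 90)
  expect_error(atriaPET:::validatePhantomSpec(sp2), "beyond the grid")
})

test_that("voxelized structure masks are pairwise disjoint and volumes exact", {
  tr <- studyPhantom()$truth
  masks <- tr$masks
  total <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  expect_true(all(total <= 1L))
  voxMl <- prod(voxelSpacing(studyPhantom()$series)) / 1000
  for (nm in names(masks))
    expect_equal(tr$volumes_ml[[nm]], sum(masks[[nm]]) * voxMl)
})

test_that("a 20 mm LA sphere at 2 mm voxels recovers the analytic volume", {
  sp <- phantomSpec(la_radius = 20, noise_scale = 0)
  masks <- atriaPET:::voxelizeGeometry(sp)
  vol <- sum(masks$la) * prod(sp$voxel_size) / 1000
  expect_lt(abs(vol / (4 / 3 * pi * 2^3) - 1), 0.02)
})

test_that("voxelized volume error decreases monotonically with voxel size", {
  analytic <- 4 / 3 * pi * 2.6^3 # default 26 mm LA sphere, in mL
  err <- vapply(c(4, 2, 1), function(h) {
    sp <- phantomSpec(grid_shape = rep(192 / h, 3), voxel_size = h)
    masks <- atriaPET:::voxelizeGeometry(sp)
    abs(sum(masks$la) * h^3 / 1000 - analytic)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("phantom generation is bit-reproducible and seed-sensitive", {
  sp <- phantomSpec(grid_shape = c(32, 32, 32), voxel_size = 6,
                    noise_scale = 1, rng_seed = 7L)
  a <- generatePhantom(sp)$series
  b <- generatePhantom(sp)$series
  expect_identical(seriesData(a), seriesData(b))
  sp2 <- phantomSpec(grid_shape = c(32, 32, 32), voxel_size = 6,
                     noise_scale = 1, rng_seed = 8L)
  expect_false(identical(seriesData(a),
                         seriesData(generatePhantom(sp2)$series)))
})

test_that("noise-free structure TACs reproduce the injected centroids", {
  ph <- studyPhantom()
  sch <- studySchedule()
  half_frame <- min(sch$duration) / 2
  for (nm in c("svc", "ra", "rv_cavity", "la", "lv_cavity", "aorta")) {
    p <- extractFirstPassPeak(ph$truth$tacs[[nm]], sch)
    tm <- peakMetrics(p)[["t_mid"]]
    expect_lt(abs(tm - ph$truth$centroid_s[[nm]]), half_frame,
              label = paste(nm, "centroid"))
  }
})

test_that("a noise-free myocardial voxel TAC equals the forward model", {
  ph <- studyPhantom()
  # unblurred structure TAC stored in the truth equals simulateTissueTac
  sp <- ph$truth$spec
  sch <- sp$frame_schedule
  tEnd <- sum(sch$duration[nrow(sch)], sch$start[nrow(sch)])
  tFine <- seq(0, tEnd, by = sp$fine_dt)
  caFine <- atriaPET:::structureCurve(tFine, sp$bolus$lv_cavity, sp$recirc)
  crvFine <- atriaPET:::structureCurve(tFine, sp$bolus$rv_cavity, sp$recirc)
  tp <- sp$tissue$lv_myocardium
  ref <- simulateTissueTac(tp$mbf, tp$ptf, tp$va, tp$vrv, caFine, crvFine,
                           sch, input_time = tFine)
  expect_equal(ph$truth$tacs$lv_myocardium, ref, tolerance = 1e-3)
})
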