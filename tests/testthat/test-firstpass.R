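# First-pass peak extraction, centroid/area metrics, parametric maps and
# the blood mask.

uniformSchedule <- function(n, dt = 1)
  data.frame(start = (0:(n - 1)) * dt, duration = rep(dt, n))

# Spec-literal brute force: among all contiguous segments containing the
# window maximum whose stepwise extension obeys the stopping rules, the
# extractor's segment is the maximal one.
bruteForceSegment <- function(tac, sch, window_s = 120, tail_frac = 0.1,
                              recirc_frac = 0.5) {
  mid <- sch$start + sch$duration / 2
  wlast <- max(which(mid <= window_s))
  i0 <- which.max(tac[seq_len(wlast)])
  peak <- tac[i0]
  okStep <- function(curIdx, nxtIdx) {
    nxt <- tac[nxtIdx]; cur <- tac[curIdx]
    if (nxt < tail_frac * peak) return(FALSE)
    if (nxt > cur && cur < recirc_frac * peak) return(FALSE)
    TRUE
  }
  valid <- function(L, R) {
    if (L > i0 || R < i0 || L < 1 || R > wlast) return(FALSE)
    if (i0 > L) for (j in seq(i0, L + 1)) if (!okStep(j, j - 1)) return(FALSE)
    if (i0 < R) for (j in seq(i0, R - 1)) if (!okStep(j, j + 1)) return(FALSE)
    TRUE
  }
  best <- c(i0, i0)
  for (L in 1:i0) for (R in i0:wlast)
    if (valid(L, R) && (R - L) > (best[2] - best[1])) best <- c(L, R)
  best
}

test_that("unimodal and degenerate TACs are handled as specified", {
  sch <- uniformSchedule(10)
  tri <- c(0, 1, 4, 9, 4, 1, 0, 0, 0, 0)
  p <- extractFirstPassPeak(tri, sch)
  expect_equal(range(p$frames), c(2, 6)) # whole rise-fall above 10% tail
  m <- peakMetrics(p)
  expect_equal(m[["t_mid"]], 3.5) # symmetric about the apex frame mid
  expect_null(extractFirstPassPeak(rep(0, 10), sch))
})

test_that("recirculation bumps are cut at the inter-peak local minimum", {
  sch <- uniformSchedule(40)
  t <- sch$start + 0.5
  tac <- bolusCurve(t, 5, 3, 1.5, 100) + bolusCurve(t, 20, 3, 3, 15)
  p <- extractFirstPassPeak(tac, sch)
  ref <- bruteForceSegment(tac, sch)
  expect_equal(range(p$frames), ref)
  # segment must end before the recirculation peak
  expect_lt(max(p$frames), which.max(bolusCurve(t, 20, 3, 3, 15)))
})

test_that("extractor matches the brute-force oracle on random TACs", {
  set.seed(11)
  sch <- defaultFrameSchedule()
  mid <- sch$start + sch$duration / 2
  for (i in 1:50) {
    tac <- bolusCurve(mid, runif(1, 3, 40), runif(1, 2, 4),
                      runif(1, 1, 3), runif(1, 20, 150)) +
      abs(rnorm(22, 0, 2))
    p <- extractFirstPassPeak(tac, sch)
    if (is.null(p)) next
    expect_equal(range(p$frames), bruteForceSegment(tac, sch))
  }
})

test_that("peak metrics follow the duration-weighted centroid definition", {
  sch <- uniformSchedule(9)
  p <- extractFirstPassPeak(c(0, 1, 2, 1, 0, 0, 0, 0, 0), sch,
                            min_peak_abs = 0.1)
  expect_equal(peakMetrics(p)[["t_mid"]], 2.5) # symmetric
  # single frame
  p1 <- structure(list(frames = 3L, values = 7, mid_s = 2.5,
                       duration_s = 10), class = "FirstPassPeak")
  m1 <- peakMetrics(p1)
  expect_equal(m1[["auc"]], 70)
  expect_equal(m1[["t_mid"]], 2.5)
  # finely framed gamma variate: analytic centroid t0 + beta(alpha+1).
  # A permissive tail cutoff isolates the centroid formula from the
  # default 10% tail truncation (which biases slow tails by ~0.6 s,
  # still well inside the half-frame bound of the clinical schedule).
  schF <- uniformSchedule(120)
  tacF <- bolusCurve(schF$start + 0.5, 10, 3, 4, 100)
  mF <- peakMetrics(extractFirstPassPeak(tacF, schF, window_s = 120,
                                         tail_frac = 0.01))
  expect_lt(abs(mF[["t_mid"]] - 26), 0.5)
  expect_error(peakMetrics(structure(list(frames = 1L, values = 0,
                                          mid_s = 1, duration_s = 1),
                                     class = "FirstPassPeak")),
               "undefined centroid")
})

test_that("t_mid is shift-equivariant and AUC scale-equivariant", {
  sch <- uniformSchedule(60)
  t <- sch$start + 0.5
  set.seed(21)
  for (i in 1:10) {
    t0 <- runif(1, 5, 20)
    shift <- sample(1:10, 1)
    amp <- runif(1, 10, 100)
    k <- runif(1, 0.5, 4)
    tac <- bolusCurve(t, t0, 3, 2, amp)
    m0 <- peakMetrics(extractFirstPassPeak(tac, sch))
    ms <- peakMetrics(extractFirstPassPeak(c(rep(0, shift),
                                             head(tac, -shift)), sch))
    expect_equal(ms[["t_mid"]], m0[["t_mid"]] + shift, tolerance = 1e-9)
    mk <- peakMetrics(extractFirstPassPeak(k * tac, sch))
    expect_equal(mk[["auc"]], k * m0[["auc"]], tolerance = 1e-9)
    expect_equal(mk[["t_mid"]], m0[["t_mid"]], tolerance = 1e-9)
  }
})

test_that("the vectorized map extractor equals the per-TAC extractor", {
  set.seed(31)
  sch <- defaultFrameSchedule()
  mid <- sch$start + sch$duration / 2
  n <- 300
  V <- t(vapply(seq_len(n), function(i) {
    amp <- sample(c(0, runif(1, 1, 120)), 1, prob = c(0.2, 0.8))
    bolusCurve(mid, runif(1, 3, 60), runif(1, 2, 4), runif(1, 1, 3),
               amp) + abs(rnorm(22, 0, 0.5))
  }, numeric(22)))
  vec <- atriaPET:::extractPeaksMatrix(V, sch)
  for (i in seq_len(n)) {
    p <- extractFirstPassPeak(V[i, ], sch)
    if (is.null(p)) {
      expect_false(vec$detected[i])
    } else {
      m <- peakMetrics(p)
      expect_true(vec$detected[i])
      expect_equal(vec$tmid[i], m[["t_mid"]])
      expect_equal(vec$auc[i], m[["auc"]])
    }
  }
})

test_that("parametric maps recover the injected transit times and order", {
  ph <- studyPhantom()
  res <- studyPipeline()
  maps <- res$maps
  half_frame <- min(studySchedule()$duration) / 2
  # LA-interior voxels (eroded against blur) sit at the LA centroid
  laCore <- atriaPET:::erode3d(ph$truth$masks$la, 2)
  expect_true(all(abs(maps@tmid[laCore] - ph$truth$centroid_s["la"]) <
                    half_frame))
  meds <- vapply(c("ra", "rv_cavity", "lungs", "la", "lv_cavity", "aorta"),
                 function(nm) structureMedian(maps@tmid,
                                              ph$truth$masks[[nm]]),
                 numeric(1))
  expect_true(meds["ra"] <= meds["rv_cavity"] + 1e-9)
  expect_lt(meds["rv_cavity"], meds["lungs"])
  expect_lt(meds["lungs"], meds["la"])
  expect_lt(meds["la"], meds["lv_cavity"])
  expect_true(meds["lv_cavity"] <= meds["aorta"] + 1e-9)
})

test_that("normalized AUC is 1 over the LV cavity and gates the blood mask", {
  ph <- studyPhantom()
  res <- studyPipeline()
  maps <- res$maps
  lvCore <- atriaPET:::erode3d(ph$truth$masks$lv_cavity, 2)
  expect_equal(mean(maps@aucNorm[lvCore]), 1, tolerance = 0.01)
  blood <- bloodMask(maps)
  # cavity interiors are blood; myocardium interiors are not
  for (nm in c("lv_cavity", "rv_cavity", "la", "ra")) {
    core <- atriaPET:::erode3d(ph$truth$masks[[nm]], 2)
    expect_true(all(blood[core]), label = paste(nm, "in blood mask"))
  }
  myoCore <- atriaPET:::erode3d(ph$truth$masks$lv_myocardium |
                                  ph$truth$masks$rv_myocardium, 1)
  expect_equal(sum(blood & myoCore), 0)
})

test_that("blood-mask thresholds follow the 2/3 AUC and 1.5 min rules", {
  d <- c(3, 1, 1)
  mk <- function(auc_norm, tmid) {
    m <- new("ParametricMaps", tmid = array(tmid, d),
             auc = array(auc_norm * 600, d),
             detected = array(TRUE, d), aucNorm = array(auc_norm, d),
             aucReference = 600, spacing = c(2, 2, 2))
    bloodMask(m)[1]
  }
  expect_true(mk(0.8, 60))
  expect_false(mk(0.5, 60))
  expect_false(mk(0.9, 120))
  m <- new("ParametricMaps", tmid = array(1, d), auc = array(1, d),
           detected = array(TRUE, d), aucNorm = NULL,
           aucReference = NA_real_, spacing = c(2, 2, 2))
  expect_error(bloodMask(m), "normalized")
})
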