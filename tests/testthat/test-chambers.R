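# Short-axis reorientation, myocardium profiling, cavity extraction and
# chamber statistics.

test_that("the long axis is recovered for axial and rotated phantoms", {
  res <- studyPipeline()
  ax <- res$transform$longAxis
  ang0 <- acos(min(abs(sum(ax * c(0, 0, 1))), 1)) * 180 / pi
  expect_lt(ang0, 5)
  res30 <- rotatedPipeline()
  truthAxis <- as.numeric(atriaPET:::rotY(30) %*% c(0, 0, 1))
  ang30 <- acos(min(abs(sum(res30$transform$longAxis * truthAxis)), 1)) *
    180 / pi
  expect_lt(ang30, 5)
})

test_that("forward-then-inverse resampling preserves a mask", {
  res <- rotatedPipeline()
  mask <- rotatedPhantom()$truth$masks$lv_cavity
  sa <- applyTransform(mask, res$transform, "nearest")
  back <- applyTransform(sa, res$transform, "nearest", "inverse")
  overlap <- sum(back & mask) / sum(mask)
  expect_gt(overlap, 0.95)
})

test_that("LV myocardium profiling overlaps the true wall", {
  ph <- studyPhantom()
  res <- studyPipeline()
  lvMyo <- labelMask(res$labels, "lv_myocardium")
  expect_gt(diceCoefficient(lvMyo, ph$truth$masks$lv_myocardium), 0.7)
})

test_that("RV segmentation stays clear of the LV cavity", {
  ph <- studyPhantom()
  res <- studyPipeline()
  rvMyo <- labelMask(res$labels, "rv_myocardium")
  expect_equal(sum(rvMyo & ph$truth$masks$lv_cavity), 0)
  expect_gt(diceCoefficient(rvMyo, ph$truth$masks$rv_myocardium), 0.5)
})

test_that("a phantom without perfusable tissue fails segmentation", {
  res <- studyPipeline()
  km <- res$kmaps
  km0 <- new("KineticMaps", mbf = km@mbf, ptf = array(0, dim(km@ptf)),
             va = km@va, vrv = km@vrv, rss = km@rss, fitted = km@fitted,
             spacing = km@spacing)
  expect_error(segmentMyocardium(km0, "LV"), "segmentation failure")
})

test_that("cavity extraction matches the analytic shell geometry", {
  # spherical shell, inner radius 30 mm: cavity = concentric ball ~17 mm
  d <- c(48, 48, 48)
  sp <- c(3, 3, 3)
  ctr <- (d - 1) * sp / 2
  cm <- atriaPET:::voxelCoordsMm(d, sp)
  R2 <- outer(outer((cm$x - ctr[1])^2, (cm$y - ctr[2])^2, `+`),
              (cm$z - ctr[3])^2, `+`)
  shell <- R2 >= 30^2 & R2 <= 40^2
  cav <- extractCavities(shell, shell, sp)$lv_cavity
  rmax <- sqrt(max(R2[cav]))
  expect_lt(abs(rmax - 17), 3.1) # inner radius minus 13 mm, voxelized
  expect_equal(sum(cav & shell), 0)
  # exhaustive per-voxel distance oracle
  myoIdx <- which(shell, arr.ind = TRUE)
  Pmyo <- sweep(myoIdx - 1, 2, sp, `*`)
  inner <- which(R2 < 30^2)
  innerIdx <- arrayInd(inner, d)
  Pin <- sweep(innerIdx - 1, 2, sp, `*`)
  brute <- array(FALSE, d)
  for (s in seq(1, nrow(Pin), by = 4000)) {
    ii <- s:min(s + 3999, nrow(Pin))
    D2 <- outer(rowSums(Pin[ii, , drop = FALSE]^2), rowSums(Pmyo^2), `+`) -
      2 * Pin[ii, , drop = FALSE] %*% t(Pmyo)
    brute[inner[ii]] <- sqrt(pmax(apply(D2, 1, min), 0)) >= 13
  }
  expect_identical(cav, brute)
})

test_that("a 12 mm inner radius leaves no cavity", {
  d <- c(24, 24, 24)
  sp <- c(2, 2, 2)
  ctr <- (d - 1) * sp / 2
  cm <- atriaPET:::voxelCoordsMm(d, sp)
  R2 <- outer(outer((cm$x - ctr[1])^2, (cm$y - ctr[2])^2, `+`),
              (cm$z - ctr[3])^2, `+`)
  shell <- R2 >= 12^2 & R2 <= 20^2
  expect_warning( # once per ventricle side
    expect_warning(cav <- extractCavities(shell, shell, sp)$lv_cavity,
                   "empty cavity"),
    "empty cavity")
  expect_equal(sum(cav), 0)
})

test_that("pipeline cavities are disjoint from the myocardium", {
  res <- studyPipeline()
  expect_equal(sum(labelMask(res$labels, "lv_cavity") &
                     labelMask(res$labels, "lv_myocardium")), 0)
  expect_equal(sum(labelMask(res$labels, "rv_cavity") &
                     labelMask(res$labels, "rv_myocardium")), 0)
})

test_that("chamber statistics reproduce the injected timing", {
  ph <- studyPhantom()
  st <- studyPipeline()$stats
  expect_lt(st$t_rv, st$t_lv)
  half_frame <- min(studySchedule()$duration) / 2
  expect_lt(abs(st$t_lv - ph$truth$centroid_s[["lv_cavity"]]), half_frame)
  expect_lt(abs(st$t_rv - ph$truth$centroid_s[["rv_cavity"]]), half_frame)
  expect_gt(st$auc_lv, 0)
  expect_gt(st$auc_rv, 0)
  expect_error(chamberStats(studyPhantom()$series,
                            array(FALSE, c(64, 64, 64)),
                            ph$truth$masks$rv_cavity), "empty LV")
})

test_that("segmentation is stable under a rotation the reorientation recovers", {
  res0 <- studyPipeline()
  res30 <- rotatedPipeline()
  # map the rotated result back into the unrotated phantom frame
  d <- dim(res30$labels@labels)
  sp <- voxelSpacing(rotatedPhantom()$series)
  ctr <- (d - 1) * sp / 2
  R <- atriaPET:::rotY(30)
  cm <- atriaPET:::voxelCoordsMm(d, sp)
  P <- cbind(rep(cm$x, times = d[2] * d[3]) - ctr[1],
             rep(rep(cm$y, each = d[1]), times = d[3]) - ctr[2],
             rep(cm$z, each = d[1] * d[2]) - ctr[3])
  src <- P %*% t(R) # forward-rotated sampling points
  coords <- sweep(sweep(src, 2, ctr, `+`), 2, sp, `/`) + 1
  for (structure in c("la", "ra")) {
    m30 <- atriaPET:::nearestNeighbour(labelMask(res30$labels, structure),
                                       coords)
    unrot <- array(as.logical(m30), d)
    expect_gt(diceCoefficient(unrot, labelMask(res0$labels, structure)),
              0.9, label = paste(structure, "rotation stability"))
  }
})
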