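# End-to-end orchestration: first-pass maps -> input functions -> kinetic
# maps -> ventricular segmentation -> atrial segmentation -> report; and
# the phantom test-retest repeatability experiment.

#' Pipeline configuration
#'
#' Aggregates every tunable constant of the pipeline with its default:
#' the blood-mask thresholds (AUC > 2/3 of the LV cavity, t_mid < 90 s),
#' the cavity margin (13 mm), the fixed water distribution volume
#' (0.91 mL/g), the heartbeat gate heart rate (60 bpm) and the
#' clustering/profiling/split parameters.
#'
#' @param ... overrides for any default listed below.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    # first pass
    peak_window_s = 120, peak_tail_frac = 0.10, peak_recirc_frac = 0.5,
    min_peak_frac = 5, min_peak_abs = 0.5,
    auc_blood_frac = 2 / 3, tmid_blood_max_s = 90,
    # clustering
    cluster_k = 6L, cluster_seed = 1L, cluster_auc_quantile = 0.75,
    min_av_lag_s = 4, high_auc_frac = 2 / 3, art_window_s = 2,
    lung_auc_lo = 0.15, lung_auc_hi = 0.5,
    # kinetics
    v_t = 0.91, mbf_grid_min = 0.1, mbf_grid_max = 5.0, mbf_grid_n = 100L,
    fine_dt = 1.0,
    # chambers
    va_component_thresh = 0.5, profile_n_angles = 36L,
    profile_r_max_mm = 60, profile_r_step_mm = 1,
    profile_ridge_frac = 0.5, profile_ptf_min = 0.1,
    cavity_margin_mm = 13,
    # atria
    heart_rate_bpm = 60, min_component_ml = 5,
    lvot_r0_mm = 5, lvot_rmax_mm = 30, lvot_rstep_mm = 1,
    tube_area_max_cm2 = 6, tube_circ_min = 0.6, tube_min_run = 3L,
    # subject
    height_cm = 170, weight_kg = 70
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  stopifnot(cfg$auc_blood_frac > 0, cfg$tmid_blood_max_s > 0,
            cfg$cavity_margin_mm > 0, cfg$v_t > 0,
            cfg$heart_rate_bpm > 0, cfg$cluster_k >= 3)
  structure(cfg, class = "PipelineConfig")
}

#' Run the full atrial-volume pipeline
#'
#' Executes first-pass parametric mapping, input-function clustering,
#' kinetic map fitting, short-axis reorientation, ventricular myocardium
#' and cavity segmentation, AUC normalization to the LV cavity, atrial
#' segmentation with bolus-timing gates, and volume reporting. The run is
#' deterministic given the series and configuration. Each stage's key
#' scalars are collected in a structured log.
#'
#' @param series a [DynamicSeries-class].
#' @param config a [pipelineConfig()].
#' @return list of class `PipelineResult` with `report`
#'   ([VolumeReport-class]), `labels` ([ChamberLabelMap-class]), `maps`,
#'   `kmaps`, `inputs`, `stats`, `transform`, and `log` (named scalars).
#' @export
runPipeline <- function(series, config = pipelineConfig()) {
  stopifnot(is(series, "DynamicSeries"), inherits(config, "PipelineConfig"))
  sch <- data.frame(start = frameStart(series),
                    duration = frameDuration(series))
  sp <- voxelSpacing(series)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  maps <- stage("firstpass", computeParametricMaps(
    series, window_s = config$peak_window_s,
    tail_frac = config$peak_tail_frac,
    recirc_frac = config$peak_recirc_frac,
    min_peak_frac = config$min_peak_frac,
    min_peak_abs = config$min_peak_abs))
  stage("firstpass", if (sum(maps@detected) == 0)
    stop("no first-pass peaks detected in the series"))
  inputs <- stage("input_functions", clusterInputFunctions(
    series, maps, k = config$cluster_k, seed = config$cluster_seed,
    auc_quantile = config$cluster_auc_quantile,
    min_av_lag_s = config$min_av_lag_s,
    high_auc_frac = config$high_auc_frac,
    art_window_s = config$art_window_s))
  kcfg <- kineticModelConfig(
    v_t = config$v_t,
    mbf_grid = logspace(config$mbf_grid_min, config$mbf_grid_max,
                        config$mbf_grid_n),
    fine_dt = config$fine_dt)
  kmaps <- stage("kinetics", fitParametricMaps(series, inputs, kcfg,
                                               maps@detected))
  tr <- stage("chambers", reorientShortAxis(
    kmaps, inputs, va_thresh = config$va_component_thresh))
  kmapsSA <- new("KineticMaps",
                 mbf = applyTransform(kmaps@mbf, tr),
                 ptf = applyTransform(kmaps@ptf, tr),
                 va = applyTransform(kmaps@va, tr),
                 vrv = applyTransform(kmaps@vrv, tr),
                 rss = applyTransform(kmaps@rss, tr),
                 fitted = applyTransform(kmaps@fitted, tr, "nearest"),
                 spacing = sp)
  myoLvSA <- stage("chambers", segmentMyocardium(
    kmapsSA, "LV", center_thresh = config$va_component_thresh,
    n_angles = config$profile_n_angles,
    r_max_mm = config$profile_r_max_mm,
    r_step_mm = config$profile_r_step_mm,
    ridge_frac = config$profile_ridge_frac,
    ptf_min = config$profile_ptf_min))
  myoRvSA <- stage("chambers", segmentMyocardium(
    kmapsSA, "RV", center_thresh = config$va_component_thresh,
    n_angles = config$profile_n_angles,
    r_max_mm = config$profile_r_max_mm,
    r_step_mm = config$profile_r_step_mm,
    ridge_frac = config$profile_ridge_frac,
    ptf_min = config$profile_ptf_min))
  cav <- stage("chambers", extractCavities(
    myoLvSA, myoRvSA, sp, margin_mm = config$cavity_margin_mm))
  lvCavN <- applyTransform(cav$lv_cavity, tr, "nearest", "inverse")
  rvCavN <- applyTransform(cav$rv_cavity, tr, "nearest", "inverse")
  stats <- stage("chambers", chamberStats(series, lvCavN, rvCavN))
  maps <- normalizeAUC(maps, stats$auc_lv)
  lung <- stage("input_functions", estimateLungTmid(
    inputs, maps, sch, auc_lo = config$lung_auc_lo,
    auc_hi = config$lung_auc_hi))
  blood <- bloodMask(maps, auc_frac = config$auc_blood_frac,
                     tmid_max_s = config$tmid_blood_max_s)
  lvot <- stage("atria", lvotAxis(cav$lv_cavity, tr))
  laRes <- stage("atria", segmentLeftAtrium(
    blood, maps, stats, lung$t_lungs, lvCavN, lvot,
    heart_rate = config$heart_rate_bpm,
    min_component_ml = config$min_component_ml,
    r0_mm = config$lvot_r0_mm, rmax_mm = config$lvot_rmax_mm,
    rstep_mm = config$lvot_rstep_mm))
  raRes <- stage("atria", segmentRightAtrium(
    blood, maps, stats, rvCavN, laRes$la, laRes$aorta,
    heart_rate = config$heart_rate_bpm,
    tube_area_max_cm2 = config$tube_area_max_cm2,
    tube_circ_min = config$tube_circ_min,
    tube_min_run = config$tube_min_run))
  prov <- c(la = if ("la_aorta_split_failed" %in% laRes$flags)
    "fallback" else "auto",
    ra = "auto",
    lungs = if (lung$fallback) "fallback" else "auto")
  labels <- buildChamberLabelMap(
    list(lv_myocardium = applyTransform(myoLvSA, tr, "nearest", "inverse"),
         rv_myocardium = applyTransform(myoRvSA, tr, "nearest", "inverse"),
         lv_cavity = lvCavN, rv_cavity = rvCavN,
         la = laRes$la, ra = raRes$ra,
         aorta = laRes$aorta, svc = raRes$svc),
    sp, provenance = prov)
  flags <- c(stats$flags, laRes$flags, raRes$flags)
  report <- atrialVolumeReport(labels, config$height_cm, config$weight_kg,
                               stats, lung$t_lungs, flags = flags)
  log <- c(t_rv_s = stats$t_rv, t_lungs_s = lung$t_lungs,
           t_lv_s = stats$t_lv, auc_lv = stats$auc_lv,
           lav_ml = report@lavMl, rav_ml = report@ravMl,
           n_blood_voxels = sum(blood))
  structure(list(report = report, labels = labels, maps = maps,
                 kmaps = kmaps, inputs = inputs, stats = stats,
                 transform = tr, t_lungs = lung$t_lungs, log = log),
            class = "PipelineResult")
}

#' Phantom test-retest repeatability experiment
#'
#' Generates `n_pairs` phantom subjects whose left-atrial radius spans
#' `la_radius_range` (an inter-subject volume spread well above 30%),
#' simulates each subject twice with independent noise realizations,
#' runs the full pipeline on every scan and feeds the paired LAV/RAV
#' estimates to [repeatabilityStats()]. Failed replicates are recorded
#' and their pair dropped.
#'
#' @param n_pairs number of subjects (>= 2).
#' @param seed master seed; per-scan seeds are derived deterministically.
#' @param grid_shape,voxel_size phantom grid (the default keeps the
#'   192 mm field of view at a coarser sampling to keep the experiment
#'   fast).
#' @param la_radius_range range of LA radii across subjects (mm).
#' @param noise_scale phantom noise level.
#' @param config a [pipelineConfig()].
#' @return list with `table` (subject, lav_test, lav_retest, rav_test,
#'   rav_retest), `lav` and `rav` repeatability statistics, and
#'   `n_failed`.
#' @export
runTestRetest <- function(n_pairs = 20, seed = 1L,
                          grid_shape = c(64, 64, 64), voxel_size = 3,
                          la_radius_range = c(20, 32), noise_scale = 1,
                          config = pipelineConfig()) {
  stopifnot(n_pairs >= 2)
  radii <- seq(la_radius_range[1], la_radius_range[2],
               length.out = n_pairs)
  rows <- list()
  n_failed <- 0L
  for (i in seq_len(n_pairs)) {
    vols <- tryCatch({
      one <- function(scan) {
        sp <- phantomSpec(grid_shape = grid_shape,
                          voxel_size = voxel_size,
                          la_radius = radii[i],
                          noise_scale = noise_scale,
                          rng_seed = (seed * 1000L + i * 7L + scan) %%
                            .Machine$integer.max)
        res <- runPipeline(generatePhantom(sp)$series, config)
        c(res$report@lavMl, res$report@ravMl)
      }
      cbind(one(1L), one(2L))
    }, error = function(e) {
      warning("pair ", i, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(vols)) { n_failed <- n_failed + 1L; next }
    rows[[length(rows) + 1L]] <-
      data.frame(subject = i, lav_test = vols[1, 1],
                 lav_retest = vols[1, 2], rav_test = vols[2, 1],
                 rav_retest = vols[2, 2])
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) < 2)
    stop("fewer than 2 successful pairs")
  list(table = tab,
       lav = repeatabilityStats(data.frame(subject = tab$subject,
                                           test = tab$lav_test,
                                           retest = tab$lav_retest)),
       rav = repeatabilityStats(data.frame(subject = tab$subject,
                                           test = tab$rav_test,
                                           retest = tab$rav_retest)),
       n_failed = n_failed)
}
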