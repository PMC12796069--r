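# NIfTI / JSON / CSV input-output for series, maps, labels and reports.

#' Write a dynamic series as 4D NIfTI plus a frame-timing sidecar
#'
#' @param series a [DynamicSeries-class].
#' @param image_path output NIfTI path (.nii or .nii.gz).
#' @param timing_path output JSON sidecar path; fields `frame_start_s`
#'   and `frame_duration_s`.
#' @return invisibly, the two paths.
#' @export
writeDynamicSeries <- function(series, image_path, timing_path) {
  img <- RNifti::asNifti(seriesData(series))
  RNifti::pixdim(img) <- c(voxelSpacing(series), 1)
  RNifti::writeNifti(img, image_path)
  jsonlite::write_json(
    list(frame_start_s = frameStart(series),
         frame_duration_s = frameDuration(series)),
    timing_path, digits = NA)
  invisible(c(image_path, timing_path))
}

#' Load a dynamic series from NIfTI plus its frame-timing sidecar
#'
#' @param image_path 4D NIfTI path.
#' @param timing_path JSON sidecar with `frame_start_s`,
#'   `frame_duration_s` (seconds).
#' @return a validated [DynamicSeries-class].
#' @export
loadDynamicSeries <- function(image_path, timing_path) {
  if (!file.exists(image_path)) stop("image file not found: ", image_path)
  if (!file.exists(timing_path)) stop("timing file not found: ", timing_path)
  img <- RNifti::readNifti(image_path)
  timing <- jsonlite::read_json(timing_path, simplifyVector = TRUE)
  if (!all(c("frame_start_s", "frame_duration_s") %in% names(timing)))
    stop("format error: timing sidecar must contain frame_start_s and ",
         "frame_duration_s")
  arr <- array(as.numeric(img), dim(img)) # plain array, no image class
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 4L)
    stop("format error: expected a 4D image")
  if (dim(arr)[4] != length(timing$frame_start_s))
    stop("format error: ", dim(arr)[4], " frames in the image but ",
         length(timing$frame_start_s), " timing entries")
  sp <- RNifti::pixdim(img)[1:3]
  DynamicSeries(arr, sp, timing$frame_start_s, timing$frame_duration_s)
}

writeMap <- function(arr, spacing, path, na_fill = NA_real_) {
  a <- arr
  if (!is.na(na_fill)) a[is.na(a)] <- na_fill
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  path
}

#' Save pipeline outputs to a directory
#'
#' Writes the chamber label map (integer NIfTI + JSON legend), the
#' parametric and kinetic maps (float NIfTI, one file per parameter) and
#' the volume report (CSV and JSON). All outputs are re-loadable to equal
#' values (within float32 NIfTI precision for maps; exactly for labels
#' and the report).
#'
#' @param labels a [ChamberLabelMap-class].
#' @param maps a [ParametricMaps-class] (may be NULL).
#' @param kmaps a [KineticMaps-class] (may be NULL).
#' @param report a [VolumeReport-class].
#' @param out_dir output directory (created if missing).
#' @return named character vector of written file paths.
#' @export
saveOutputs <- function(labels, maps = NULL, kmaps = NULL, report,
                        out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sp <- voxelSpacing(labels)
  files <- c()
  if (!is.null(maps)) {
    if (!identical(dim(maps@tmid), dim(labels@labels)))
      stop("geometry error: maps and labels are on different grids")
    files["tmid"] <- writeMap(maps@tmid, sp,
                              file.path(out_dir, "tmid_s.nii.gz"))
    if (!is.null(maps@aucNorm))
      files["auc_norm"] <- writeMap(maps@aucNorm, sp,
                                    file.path(out_dir, "auc_norm.nii.gz"))
  }
  if (!is.null(kmaps)) {
    for (nm in c("mbf", "ptf", "va", "vrv"))
      files[nm] <- writeMap(slot(kmaps, nm), sp,
                            file.path(out_dir, paste0(nm, ".nii.gz")))
  }
  limg <- RNifti::asNifti(labels@labels + 0L)
  RNifti::pixdim(limg) <- sp
  files["labels"] <- file.path(out_dir, "chamber_labels.nii.gz")
  RNifti::writeNifti(limg, files[["labels"]], datatype = "int16")
  files["legend"] <- file.path(out_dir, "chamber_labels_legend.json")
  jsonlite::write_json(as.list(chamberLabelCodes()),
                       files[["legend"]], auto_unbox = TRUE)
  rep_df <- as.data.frame(report)
  files["report_csv"] <- file.path(out_dir, "volume_report.csv")
  write.csv(rep_df, files[["report_csv"]], row.names = FALSE)
  files["report_json"] <- file.path(out_dir, "volume_report.json")
  jsonlite::write_json(c(as.list(rep_df[1, seq_len(ncol(rep_df) - 1)]),
                         list(flags = report@flags)),
                       files[["report_json"]], auto_unbox = TRUE,
                       digits = NA)
  files
}

#' Save a generated phantom to a directory
#'
#' Writes the dynamic series (4D NIfTI + timing JSON), the ground-truth
#' label map (integer NIfTI, structure codes per the JSON legend) and the
#' ground-truth parameters (volumes, centroid times, tissue parameters)
#' as JSON.
#'
#' @param phantom result of [generatePhantom()].
#' @param out_dir output directory.
#' @return named character vector of written file paths.
#' @export
savePhantom <- function(phantom, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    series = file.path(out_dir, "phantom_4d.nii.gz"),
    timing = file.path(out_dir, "phantom_timing.json"),
    truth_labels = file.path(out_dir, "truth_labels.nii.gz"),
    truth_legend = file.path(out_dir, "truth_legend.json"),
    truth_params = file.path(out_dir, "truth_params.json"))
  writeDynamicSeries(phantom$series, files[["series"]], files[["timing"]])
  masks <- phantom$truth$masks
  lab <- array(0L, dim(masks[[1]]))
  for (i in seq_along(masks)) lab[masks[[i]]] <- i
  limg <- RNifti::asNifti(lab)
  RNifti::pixdim(limg) <- voxelSpacing(phantom$series)
  RNifti::writeNifti(limg, files[["truth_labels"]], datatype = "int16")
  jsonlite::write_json(as.list(stats::setNames(seq_along(masks),
                                               names(masks))),
                       files[["truth_legend"]], auto_unbox = TRUE)
  jsonlite::write_json(
    list(volumes_ml = as.list(phantom$truth$volumes_ml),
         centroid_s = as.list(phantom$truth$centroid_s),
         tissue = phantom$truth$tissue),
    files[["truth_params"]], auto_unbox = TRUE, digits = NA)
  files
}
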