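#' Accessors for atriaPET containers
#'
#' Small accessor generics used throughout the package: `seriesData` returns
#' the raw 4D array of a [DynamicSeries-class], `voxelSpacing` the voxel
#' size in mm, `frameStart`/`frameDuration`/`frameMid` the frame schedule in
#' seconds, `nFrames` the frame count, `voxelVolumeMl` the volume of one
#' voxel in mL, and `labelMask` a logical mask for one structure of a
#' [ChamberLabelMap-class].
#'
#' @param x an atriaPET object.
#' @param structure structure name, one of `names(chamberLabelCodes())`.
#' @return The accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("seriesData", function(x) standardGeneric("seriesData"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("frameStart", function(x) standardGeneric("frameStart"))
#' @rdname accessors
#' @export
setGeneric("frameDuration", function(x) standardGeneric("frameDuration"))
#' @rdname accessors
#' @export
setGeneric("frameMid", function(x) standardGeneric("frameMid"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("voxelVolumeMl", function(x) standardGeneric("voxelVolumeMl"))
#' @rdname accessors
#' @export
setGeneric("labelMask", function(x, structure) standardGeneric("labelMask"))

#' @rdname accessors
#' @export
setMethod("seriesData", "DynamicSeries", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "DynamicSeries", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "ParametricMaps", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "KineticMaps", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "ChamberLabelMap", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("frameStart", "DynamicSeries", function(x) x@frameStart)
#' @rdname accessors
#' @export
setMethod("frameDuration", "DynamicSeries", function(x) x@frameDuration)
#' @rdname accessors
#' @export
setMethod("frameMid", "DynamicSeries",
          function(x) x@frameStart + x@frameDuration / 2)
#' @rdname accessors
#' @export
setMethod("nFrames", "DynamicSeries", function(x) length(x@frameStart))
#' @rdname accessors
#' @export
setMethod("voxelVolumeMl", "DynamicSeries",
          function(x) prod(x@spacing) / 1000)
#' @rdname accessors
#' @export
setMethod("voxelVolumeMl", "ChamberLabelMap",
          function(x) prod(x@spacing) / 1000)
#' @rdname accessors
#' @export
setMethod("labelMask", "ChamberLabelMap", function(x, structure) {
  code <- chamberLabelCodes()[[structure]]
  x@labels == code
})

setMethod("show", "DynamicSeries", function(object) {
  d <- dim(object@data)
  cat("DynamicSeries:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4], "frames\n")
  cat("  spacing (mm):", paste(signif(object@spacing, 4), collapse = " x "),
      "\n")
  cat("  duration (s):",
      object@frameStart[length(object@frameStart)] +
        object@frameDuration[length(object@frameDuration)], "\n")
})

setMethod("show", "ParametricMaps", function(object) {
  cat("ParametricMaps:", paste(dim(object@tmid), collapse = " x "), "\n")
  cat("  peak-detected voxels:", sum(object@detected), "\n")
  cat("  normalized:", !is.null(object@aucNorm),
      if (is.finite(object@aucReference))
        sprintf("(AUC_LV = %.4g kBq.s/mL)", object@aucReference) else "",
      "\n")
})

setMethod("show", "KineticMaps", function(object) {
  cat("KineticMaps:", paste(dim(object@mbf), collapse = " x "),
      "-", sum(object@fitted), "fitted voxels\n")
  if (any(object@fitted))
    cat(sprintf("  median MBF %.3g mL/g/min, median PTF %.3g g/mL\n",
                median(object@mbf[object@fitted]),
                median(object@ptf[object@fitted])))
})

setMethod("show", "InputFunctions", function(object) {
  cat("InputFunctions: k =", nrow(object@clusterMeans), "clusters\n")
  cat(sprintf("  C_RV peak %.3g kBq/mL at %.3g s; C_A peak %.3g kBq/mL at %.3g s\n",
              max(object@crv), object@frameMid[which.max(object@crv)],
              max(object@ca), object@frameMid[which.max(object@ca)]))
})

setMethod("show", "ChamberLabelMap", function(object) {
  cat("ChamberLabelMap:", paste(dim(object@labels), collapse = " x "), "\n")
  codes <- chamberLabelCodes()
  vox <- vapply(codes, function(c) sum(object@labels == c), numeric(1))
  ml <- vox * prod(object@spacing) / 1000
  for (i in seq_along(codes))
    cat(sprintf("  %-14s %6d vox  %8.2f mL  [%s]\n", names(codes)[i],
                vox[i], ml[i],
                if (names(codes)[i] %in% names(object@provenance))
                  object@provenance[[names(codes)[i]]] else "auto"))
})

setMethod("show", "VolumeReport", function(object) {
  cat("VolumeReport\n")
  cat(sprintf("  LAV %.1f mL  RAV %.1f mL  (BSA %.3f m^2)\n",
              object@lavMl, object@ravMl, object@bsaM2))
  cat(sprintf("  LAVI %.1f  RAVI %.1f mL/m^2\n",
              object@laviMlM2, object@raviMlM2))
  cat(sprintf("  t_RV %.1f s  t_lungs %.1f s  t_LV %.1f s  AUC_LV %.4g\n",
              object@tRv, object@tLungs, object@tLv, object@aucLv))
  cat("  flags:", if (length(object@flags)) paste(object@flags, collapse = ", ")
      else "none", "\n")
})

#' Convert a VolumeReport to a one-row data.frame
#' @param x a [VolumeReport-class].
#' @param row.names,optional,... ignored, present for generic compatibility.
#' @return A one-row data.frame.
#' @export
as.data.frame.VolumeReport <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  data.frame(lav_ml = x@lavMl, rav_ml = x@ravMl,
             lavi_ml_m2 = x@laviMlM2, ravi_ml_m2 = x@raviMlM2,
             bsa_m2 = x@bsaM2, t_rv_s = x@tRv, t_lungs_s = x@tLungs,
             t_lv_s = x@tLv, auc_lv = x@aucLv,
             flags = paste(x@flags, collapse = ";"))
}
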