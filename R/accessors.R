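#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname voxels
#' @export
setMethod("voxels", "PhaseStack", function(x) x@voxels)

#' @rdname voxels
#' @export
setMethod("voxels", "RegionMask", function(x) x@voxels)

#' @rdname voxels
#' @export
setMethod("voxels", "FDMap", function(x) x@values)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "PhaseStack", function(x) x@spacing)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "RegionMask", function(x) x@spacing)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "FDMap", function(x) x@spacing)

#' @rdname phaseLabels
#' @export
setMethod("phaseLabels", "PhaseStack", function(x) x@phaseLabels)

#' @rdname isNormalized
#' @export
setMethod("isNormalized", "PhaseStack", function(x) x@normalized)

#' @rdname maskLabel
#' @export
setMethod("maskLabel", "RegionMask", function(x) x@label)

#' @rdname clampedFraction
#' @export
setMethod("clampedFraction", "FDMap", function(x) x@clampedFraction)

#' @rdname scalesUsed
#' @export
setMethod("scalesUsed", "FDMap", function(x) x@scalesUsed)

#' @describeIn PhaseStack Grid dimensions `(nx, ny, nz, nphase)`.
#' @param x A `PhaseStack`.
#' @export
setMethod("dim", "PhaseStack", function(x) dim(x@voxels))

#' @describeIn RegionMask Grid dimensions `(nx, ny, nz)`.
#' @param x A `RegionMask`.
#' @export
setMethod("dim", "RegionMask", function(x) dim(x@voxels))

#' @describeIn FDMap Grid dimensions `(nx, ny, nz)`.
#' @param x An `FDMap`.
#' @export
setMethod("dim", "FDMap", function(x) dim(x@values))

setMethod("show", "PhaseStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("PhaseStack: %d x %d x %d voxels, %d phases (%s)\n",
              d[1], d[2], d[3], d[4],
              paste(object@phaseLabels, collapse = ", ")))
  cat(sprintf("  spacing: %s mm; intensities: %s\n",
              paste(format(object@spacing, digits = 4), collapse = " x "),
              if (object@normalized) "portal-vein normalized (vein = 100)"
              else "Hounsfield units"))
  invisible(NULL)
})

setMethod("show", "RegionMask", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("RegionMask '%s': %d / %d voxels on a %d x %d x %d grid (%s mm)\n",
              object@label, sum(object@voxels), prod(d), d[1], d[2], d[3],
              paste(format(object@spacing, digits = 4), collapse = " x ")))
  invisible(NULL)
})

setMethod("show", "FDMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("FDMap: %d x %d x %d, FD range [%.3f, %.3f], scales {%s}\n",
              d[1], d[2], d[3], min(object@values), max(object@values),
              paste(object@scalesUsed, collapse = ",")))
  cat(sprintf("  clamped fraction: %.4g\n", object@clampedFraction))
  invisible(NULL)
})

setMethod("show", "GlobalFDResult", function(object) {
  cat(sprintf("Global FD (%s): %.4f  [log-log fit R2 = %.4f over %d scales%s]\n",
              object@roiLabel, object@fd, object@fitR2,
              length(object@logScales),
              if (object@clamped) ", clamped" else ""))
  invisible(NULL)
})

setMethod("show", "NoiseEstimate", function(object) {
  cat(sprintf("NoiseEstimate: sd = %.3f HU from %d ROI voxels\n",
              object@sdHU, object@roiVoxelCount))
  invisible(NULL)
})

setMethod("show", "ReferenceSignals", function(object) {
  cat(sprintf("ReferenceSignals: i0 = %.1f HU; ipv = %s\n", object@i0,
              paste(sprintf("%s: %.1f", names(object@ipv), object@ipv),
                    collapse = ", ")))
  invisible(NULL)
})

setMethod("show", "SizeMeasurement", function(object) {
  cat(sprintf(
    "SizeMeasurement '%s': volume %.3f mL, Feret %.2f mm, RECIST %.2f mm (%d voxels)\n",
    object@label, object@volumeMl, object@feretMm, object@recistMm,
    object@voxelCount))
  invisible(NULL)
})

setMethod("show", "AgreementStats", function(object) {
  cat(sprintf("AgreementStats (n = %d, reference - test):\n", object@n))
  cat(sprintf("  mean difference %.4g  [limits %.4g to %.4g]\n",
              object@meanDiff, object@lowerLimit, object@upperLimit))
  cat(sprintf("  test ~ reference: slope %.4g, intercept %.4g, R2 %.4f\n",
              object@corrSlope, object@corrIntercept, object@r2))
  invisible(NULL)
})

#' Tabulate a SizeMeasurement
#'
#' @param x A [SizeMeasurement-class].
#' @param row.names,optional,... Passed on as in [base::as.data.frame].
#' @return One-row data.frame with columns label, volume_ml, feret_mm,
#'   recist_mm, voxel_count.
#' @export
as.data.frame.SizeMeasurement <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(label = x@label, volume_ml = x@volumeMl, feret_mm = x@feretMm,
             recist_mm = x@recistMm, voxel_count = x@voxelCount,
             stringsAsFactors = FALSE)
}
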