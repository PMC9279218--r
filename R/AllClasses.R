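#' PhaseStack: a co-registered multiphasic CT volume
#'
#' A 4D scalar grid over three spatial axes and one contrast-enhancement
#' phase axis. Intensities are Hounsfield units before normalization and
#' portal-vein-referenced units (portal vein = 100) afterwards. All phases
#' share one spatial grid and spacing.
#'
#' @slot voxels 4D numeric array `(x, y, z, phase)`.
#' @slot spacing Numeric `(sx, sy, sz)` voxel spacing in mm, all positive.
#' @slot phaseLabels Character vector naming the phases in acquisition order,
#'   e.g. `c("unenhanced", "parenchymal", "portal_venous")`.
#' @slot normalized Logical; `TRUE` once intensities are on the portal-vein
#'   scale.
#'
#' @seealso [normalizeEnhancement()], [localFDMap()]
#' @export
setClass("PhaseStack",
  representation(voxels = "array", spacing = "numeric",
                 phaseLabels = "character", normalized = "logical"),
  prototype(normalized = FALSE))

setValidity("PhaseStack", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 4L) return("voxels must be a 4D array (x, y, z, phase)")
  if (dim(v)[4] < 2L) return("a PhaseStack needs at least 2 phases")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 positive finite numbers (mm)")
  if (length(object@phaseLabels) != dim(v)[4])
    return("phaseLabels must name each phase")
  if (anyDuplicated(object@phaseLabels))
    return("phaseLabels must be unique")
  if (length(object@normalized) != 1L)
    return("normalized must be a single flag")
  TRUE
})

#' Construct a PhaseStack
#'
#' @param voxels 4D numeric array `(x, y, z, phase)`.
#' @param spacing Numeric `(sx, sy, sz)` in mm.
#' @param phaseLabels Character phase names; defaults to the standard
#'   pancreatic protocol `unenhanced, parenchymal, portal_venous` when the
#'   stack has three phases.
#' @param normalized Logical; is the stack already on the portal-vein scale?
#' @return A [PhaseStack-class] object.
#' @examples
#' s <- PhaseStack(array(0, c(4, 4, 4, 3)), spacing = c(0.7, 0.7, 0.7))
#' dim(s)
#' @export
PhaseStack <- function(voxels, spacing,
                       phaseLabels = NULL, normalized = FALSE) {
  voxels <- as.array(voxels)
  storage.mode(voxels) <- "double"
  if (is.null(phaseLabels)) {
    np <- if (length(dim(voxels)) == 4L) dim(voxels)[4] else 0L
    phaseLabels <- if (np == 3L)
      c("unenhanced", "parenchymal", "portal_venous")
    else paste0("phase", seq_len(np))
  }
  methods::new("PhaseStack", voxels = voxels, spacing = as.numeric(spacing),
               phaseLabels = phaseLabels, normalized = normalized)
}

#' RegionMask: a binary voxel mask on a PhaseStack grid
#'
#' @slot voxels 3D logical array.
#' @slot spacing Numeric `(sx, sy, sz)` in mm.
#' @slot label Region name (`core`, `rim`, `tumour`, `pancreas`,
#'   `portal_vein`, `muscle`, or free text).
#' @export
setClass("RegionMask",
  representation(voxels = "array", spacing = "numeric", label = "character"))

setValidity("RegionMask", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 3L) return("mask voxels must be a 3D array")
  if (!is.logical(v)) return("mask voxels must be logical")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive numbers (mm)")
  if (length(object@label) != 1L) return("label must be a single string")
  TRUE
})

#' Construct a RegionMask
#'
#' @param voxels 3D array, coerced to logical (non-zero = inside).
#' @param spacing Numeric `(sx, sy, sz)` in mm.
#' @param label Region name.
#' @return A [RegionMask-class] object.
#' @export
RegionMask <- function(voxels, spacing, label = "region") {
  v <- as.array(voxels)
  storage.mode(v) <- "logical"
  methods::new("RegionMask", voxels = v, spacing = as.numeric(spacing),
               label = label)
}

#' FDMap: per-voxel local fractal dimension
#'
#' Local FD of the 4D intensity graph; values lie in `[4, 5]` (a 4D signal
#' graph embedded in 5 dimensions). Shares the spatial grid of its source
#' stack.
#'
#' @slot values 3D numeric array of FD values in `[4, 5]`.
#' @slot spacing Numeric `(sx, sy, sz)` in mm.
#' @slot clampedFraction Fraction of voxels whose regression slope fell
#'   outside the theoretical range and was clipped.
#' @slot scalesUsed Integer blanket scales used in the per-window fit.
#' @export
setClass("FDMap",
  representation(values = "array", spacing = "numeric",
                 clampedFraction = "numeric", scalesUsed = "integer"))

setValidity("FDMap", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L) return("values must be a 3D array")
  if (any(v < 4 - 1e-9 | v > 5 + 1e-9, na.rm = TRUE))
    return("FD values must lie in [4, 5]")
  if (object@clampedFraction < 0 || object@clampedFraction > 1)
    return("clampedFraction must be in [0, 1]")
  if (length(object@scalesUsed) < 2L)
    return("at least two blanket scales are required")
  TRUE
})

#' GlobalFDResult: a single FD scalar for a whole region of interest
#'
#' @slot fd FD scalar in `[4, 5]` (after clamping).
#' @slot logScales Log blanket scales entering the regression.
#' @slot logAreas Log surface measures entering the regression.
#' @slot fitR2 Coefficient of determination of the log-log fit.
#' @slot clamped Was the raw estimate clipped into `[4, 5]`?
#' @slot roiLabel Label of the region the FD summarizes.
#' @export
setClass("GlobalFDResult",
  representation(fd = "numeric", logScales = "numeric", logAreas = "numeric",
                 fitR2 = "numeric", clamped = "logical", roiLabel = "character"))

setValidity("GlobalFDResult", function(object) {
  if (object@fd < 4 - 1e-9 || object@fd > 5 + 1e-9)
    return("fd must lie in [4, 5]")
  if (length(object@logScales) != length(object@logAreas) ||
      length(object@logScales) < 2L)
    return("need >= 2 matching (scale, area) pairs")
  if (object@fitR2 < -1e-9 || object@fitR2 > 1 + 1e-9)
    return("fitR2 must lie in [0, 1]")
  TRUE
})

#' NoiseEstimate: image noise measured in a muscle ROI
#'
#' @slot sdHU Sample standard deviation of HU in the ROI.
#' @slot roiVoxelCount Number of voxels entering the estimate.
#' @export
setClass("NoiseEstimate",
  representation(sdHU = "numeric", roiVoxelCount = "integer"))

setValidity("NoiseEstimate", function(object) {
  if (object@sdHU < 0) return("sdHU must be >= 0")
  if (object@roiVoxelCount < 2L) return("need >= 2 ROI voxels")
  TRUE
})

#' ReferenceSignals: portal-vein intensities anchoring the normalization
#'
#' `i0` is the unenhanced portal-vein signal; `ipv` holds the portal-vein
#' signal per contrast phase (named by phase label).
#'
#' @slot i0 Scalar HU.
#' @slot ipv Named numeric, HU per contrast phase.
#' @export
setClass("ReferenceSignals",
  representation(i0 = "numeric", ipv = "numeric"))

setValidity("ReferenceSignals", function(object) {
  if (length(object@i0) != 1L || !is.finite(object@i0))
    return("i0 must be a finite scalar")
  if (length(object@ipv) < 1L || is.null(names(object@ipv)))
    return("ipv must be a named numeric vector (one entry per contrast phase)")
  if (any(abs(object@ipv - object@i0) < 1e-9))
    return("ipv must differ from i0 for every contrast phase")
  TRUE
})

#' ReferenceSignals constructor
#'
#' @param i0 Unenhanced portal-vein signal (HU).
#' @param ipv Named numeric vector of per-contrast-phase portal-vein signal.
#' @return A [ReferenceSignals-class] object.
#' @export
ReferenceSignals <- function(i0, ipv) {
  methods::new("ReferenceSignals", i0 = as.numeric(i0), ipv = ipv)
}

#' SizeMeasurement: volumetry and diameters of one segmentation
#'
#' @slot volumeMl Volume in mL (`voxelCount * voxel volume / 1000`, exact).
#' @slot feretMm Maximum 3D caliper (Feret) diameter in mm.
#' @slot recistMm Maximum in-plane axial diameter in mm.
#' @slot voxelCount Number of mask voxels.
#' @slot label Label of the measured region.
#' @export
setClass("SizeMeasurement",
  representation(volumeMl = "numeric", feretMm = "numeric",
                 recistMm = "numeric", voxelCount = "integer",
                 label = "character"))

setValidity("SizeMeasurement", function(object) {
  if (object@volumeMl < 0 || object@feretMm < 0 || object@recistMm < 0 ||
      object@voxelCount < 0)
    return("all size measurements must be non-negative")
  TRUE
})

#' AgreementStats: Bland-Altman and regression agreement of two methods
#'
#' Differences follow the reference-minus-test convention.
#'
#' @slot meanDiff Mean difference (reference - test).
#' @slot lowerLimit,upperLimit Limits of agreement `meanDiff +- 1.96 * SD`.
#' @slot propSlope,propIntercept Regression of difference on pairwise mean
#'   (proportional-bias check), each with a 95% CI attribute row.
#' @slot propCI 2x2 matrix of 95% CIs (rows slope/intercept).
#' @slot corrSlope,corrIntercept Regression of test on reference.
#' @slot corrCI 2x2 matrix of 95% CIs (rows slope/intercept).
#' @slot r2 Coefficient of determination of the test~reference regression.
#' @slot refOnTest Numeric `(slope, intercept)` of the reverse regression,
#'   provided because published agreement tables differ in orientation.
#' @slot n Number of pairs.
#' @export
setClass("AgreementStats",
  representation(meanDiff = "numeric", lowerLimit = "numeric",
                 upperLimit = "numeric", propSlope = "numeric",
                 propIntercept = "numeric", propCI = "matrix",
                 corrSlope = "numeric", corrIntercept = "numeric",
                 corrCI = "matrix", r2 = "numeric", refOnTest = "numeric",
                 n = "integer"))

setValidity("AgreementStats", function(object) {
  if (object@lowerLimit > object@meanDiff + 1e-12 ||
      object@upperLimit < object@meanDiff - 1e-12)
    return("limits of agreement must bracket the mean difference")
  if (object@r2 < -1e-9 || object@r2 > 1 + 1e-9)
    return("r2 must lie in [0, 1]")
  TRUE
})

#' PhantomTruth: ground truth accompanying a synthetic phantom
#'
#' @slot masks Named list of [RegionMask-class] objects (`core`, `rim`,
#'   `tumour`, `pancreas`, `portal_vein`, `muscle`).
#' @slot trueVolumeMl Named numeric, exact voxel-count volume per mask (mL).
#' @slot analyticVolumeMl Named numeric, analytic ellipsoid/shell volumes
#'   where defined (mL).
#' @slot trueFeretMm Named numeric, Feret diameter of each truth mask (mm).
#' @slot spec The [phantomSpec()] list the phantom was built from.
#' @export
setClass("PhantomTruth",
  representation(masks = "list", trueVolumeMl = "numeric",
                 analyticVolumeMl = "numeric", trueFeretMm = "numeric",
                 spec = "list"))
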