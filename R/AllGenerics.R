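#' @include AllClasses.R
NULL

#' Access the voxel grid of an image object
#'
#' Returns the raw array stored in a [PhaseStack-class] (4D),
#' [RegionMask-class] (3D logical) or [FDMap-class] (3D double).
#'
#' @param x An image object.
#' @return An array.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' Voxel spacing in millimetres
#'
#' @param x An image object with a spatial grid.
#' @return Numeric vector `(sx, sy, sz)` in mm.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Ordered contrast-phase labels of a stack
#'
#' @param x A [PhaseStack-class].
#' @return Character vector of phase names.
#' @export
setGeneric("phaseLabels", function(x) standardGeneric("phaseLabels"))

#' Has the stack been intensity-normalized to the portal-vein scale?
#'
#' @param x A [PhaseStack-class].
#' @return Logical flag.
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' Label of a region mask
#'
#' @param x A [RegionMask-class].
#' @return Character label (e.g. `"core"`, `"rim"`, `"portal_vein"`).
#' @export
setGeneric("maskLabel", function(x) standardGeneric("maskLabel"))

#' Fraction of local FD values clipped into the admissible range
#'
#' @param x An [FDMap-class].
#' @return Scalar in `[0, 1]`.
#' @export
setGeneric("clampedFraction", function(x) standardGeneric("clampedFraction"))

#' Blanket scales used when estimating an FD map
#'
#' @param x An [FDMap-class].
#' @return Integer vector of scale indices.
#' @export
setGeneric("scalesUsed", function(x) standardGeneric("scalesUsed"))

#' Resample an image onto an isotropic grid
#'
#' @param x A [PhaseStack-class] (linear interpolation per phase) or a
#'   [RegionMask-class] (nearest-neighbour, so no new labels are invented).
#' @param targetMm Positive scalar target spacing in mm (default 0.7).
#' @return Object of the same class on the new grid; the spatial extent in mm
#'   is preserved within one voxel.
#' @export
setGeneric("resampleIsotropic",
           function(x, targetMm = 0.7) standardGeneric("resampleIsotropic"))
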