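#' @include AllClasses.R AllGenerics.R
NULL

#' Segmentation volume in millilitres
#'
#' Exactly `voxel count * sx * sy * sz / 1000`; an empty mask measures 0 mL.
#'
#' @param mask A [RegionMask-class].
#' @return Volume in mL.
#' @examples
#' m <- RegionMask(array(TRUE, c(10, 10, 10)), c(1, 1, 1))
#' maskVolumeMl(m)  # 1 mL
#' @export
maskVolumeMl <- function(mask) {
  stopifnot(methods::is(mask, "RegionMask"))
  sum(mask@voxels) * prod(mask@spacing) / 1000
}

.maskCandidatePoints <- function(mask) {
  # every convex-hull vertex of the voxel-centre set is the first or last
  # mask voxel on its own x-grid line, so per-(y,z) extremes suffice for
  # the maximum caliper search
  idx <- which(mask@voxels, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(idx)
  key <- idx[, 2] + (idx[, 3] - 1) * dim(mask@voxels)[2]
  ord <- order(key, idx[, 1])
  idx <- idx[ord, , drop = FALSE]
  key <- key[ord]
  first <- !duplicated(key)
  last <- !duplicated(key, fromLast = TRUE)
  unique(idx[first | last, , drop = FALSE])
}

#' 3D Feret (maximum caliper) diameter
#'
#' Maximum pairwise Euclidean distance between mask voxel centres in mm;
#' independent of the orientation of the tumour's longest axis, unlike
#' in-plane measurement. Distances use the voxel-centre convention (a
#' single voxel has diameter 0). The search is reduced to per-grid-line
#' extreme voxels, which contain every convex-hull vertex.
#'
#' @param mask Non-empty [RegionMask-class].
#' @return Diameter in mm.
#' @export
feretDiameter <- function(mask) {
  stopifnot(methods::is(mask, "RegionMask"))
  pts <- .maskCandidatePoints(mask)
  if (nrow(pts) == 0L) stop("empty mask")
  mm <- sweep((pts - 1), 2, mask@spacing, `*`)
  cpp_max_pairdist(mm)
}

#' In-plane (RECIST-style) maximum diameter
#'
#' Maximum over axial (z) slices of the largest in-slice pairwise distance
#' between voxel centres, reflecting diameter measurement in the standard
#' axial plane.
#'
#' @param mask Non-empty [RegionMask-class].
#' @return Diameter in mm.
#' @export
recistDiameter <- function(mask) {
  stopifnot(methods::is(mask, "RegionMask"))
  v <- mask@voxels
  if (!any(v)) stop("empty mask")
  sp <- mask@spacing
  best <- 0
  for (z in seq_len(dim(v)[3])) {
    sl <- v[, , z]
    if (!any(sl)) next
    idx <- which(sl, arr.ind = TRUE)
    # per-row extremes capture the planar hull vertices
    ord <- order(idx[, 2], idx[, 1])
    idx <- idx[ord, , drop = FALSE]
    first <- !duplicated(idx[, 2])
    last <- !duplicated(idx[, 2], fromLast = TRUE)
    pts <- idx[first | last, , drop = FALSE]
    mm <- cbind((pts[, 1] - 1) * sp[1], (pts[, 2] - 1) * sp[2], 0)
    d <- cpp_max_pairdist(mm)
    if (d > best) best <- d
  }
  best
}

#' All size measurements for one segmentation
#'
#' @param mask A [RegionMask-class] (may be empty; diameters are then 0).
#' @return A [SizeMeasurement-class].
#' @export
measureSize <- function(mask) {
  stopifnot(methods::is(mask, "RegionMask"))
  n <- sum(mask@voxels)
  methods::new("SizeMeasurement",
               volumeMl = maskVolumeMl(mask),
               feretMm = if (n > 0) feretDiameter(mask) else 0,
               recistMm = if (n > 0) recistDiameter(mask) else 0,
               voxelCount = as.integer(n), label = mask@label)
}

#' FD-threshold segmentation from a seed point
#'
#' Reproducible automation of FD-guided segmentation: the connected
#' component (26-connectivity, permissive enough for thin rims) of
#' `{FD >= threshold}` containing the seed voxel. An empty mask results
#' when the seed itself lies below the threshold.
#'
#' @param fdmap An [FDMap-class].
#' @param threshold FD cut-off separating tumour from adjacent tissue.
#' @param seedPoint Integer voxel index `(x, y, z)`, 1-based, inside the
#'   grid.
#' @param label Label for the returned mask (default `"tumour"`).
#' @return A [RegionMask-class] on the FD map grid.
#' @export
segmentFDThreshold <- function(fdmap, threshold, seedPoint,
                               label = "tumour") {
  stopifnot(methods::is(fdmap, "FDMap"))
  d <- dim(fdmap@values)
  seedPoint <- as.integer(seedPoint)
  if (length(seedPoint) != 3L || any(seedPoint < 1L) ||
      any(seedPoint > d))
    stop("seed point outside grid")
  above <- fdmap@values >= threshold
  sel <- cpp_flood26(as.logical(above), as.integer(d), seedPoint - 1L)
  RegionMask(array(sel, d), fdmap@spacing, label)
}
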