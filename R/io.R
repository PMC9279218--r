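#' @include AllClasses.R
NULL

#' Read a 3D NIfTI volume
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return List with `voxels` (3D array) and `spacing` (mm).
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D volume, got ", length(dim(arr)), "D: ", path)
  list(voxels = arr, spacing = as.numeric(RNifti::pixdim(img))[1:3])
}

#' Write a 3D volume as NIfTI (float32)
#'
#' @param voxels 3D numeric array.
#' @param spacing Numeric `(sx, sy, sz)` in mm.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(voxels, spacing, path) {
  if (!dir.exists(dirname(path))) stop("directory does not exist: ",
                                       dirname(path))
  img <- RNifti::asNifti(voxels)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read co-registered phase volumes into a PhaseStack
#'
#' All files must share one grid and spacing (to 1e-4 mm).
#'
#' @param paths Character vector of NIfTI paths, one per phase, in
#'   acquisition order.
#' @param phaseLabels Phase names (default the standard three-phase
#'   pancreatic protocol when three files are given).
#' @return A [PhaseStack-class].
#' @export
readPhaseStack <- function(paths, phaseLabels = NULL) {
  if (length(paths) < 2L) stop("need at least 2 phase volumes")
  vols <- lapply(paths, readVolume)
  d1 <- dim(vols[[1]]$voxels)
  for (i in seq_along(vols)) {
    if (!all(dim(vols[[i]]$voxels) == d1))
      stop("grid mismatch across phases: ", paths[i])
    if (max(abs(vols[[i]]$spacing - vols[[1]]$spacing)) > 1e-4)
      stop("spacing mismatch across phases: ", paths[i])
  }
  vox <- array(0, c(d1, length(vols)))
  for (i in seq_along(vols)) vox[, , , i] <- vols[[i]]$voxels
  PhaseStack(vox, vols[[1]]$spacing, phaseLabels)
}

#' Write each phase of a stack as a NIfTI volume
#'
#' @param stack A [PhaseStack-class].
#' @param dir Output directory (must exist).
#' @param prefix Filename prefix (default `"phase"`).
#' @return Character vector of written paths, invisibly.
#' @export
writePhaseStack <- function(stack, dir, prefix = "phase") {
  stopifnot(methods::is(stack, "PhaseStack"))
  labs <- phaseLabels(stack)
  paths <- file.path(dir, paste0(prefix, "_", labs, ".nii.gz"))
  for (p in seq_along(labs))
    writeVolume(stack@voxels[, , , p], voxelSpacing(stack), paths[p])
  invisible(paths)
}

#' Read a binary NIfTI label volume as a RegionMask
#'
#' @param path NIfTI path; non-zero voxels are inside the mask.
#' @param label Region label.
#' @return A [RegionMask-class].
#' @export
readMask <- function(path, label = "region") {
  v <- readVolume(path)
  RegionMask(v$voxels != 0, v$spacing, label)
}

#' Write a RegionMask as NIfTI (uint8)
#'
#' @param mask A [RegionMask-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(methods::is(mask, "RegionMask"))
  img <- RNifti::asNifti(array(as.integer(mask@voxels), dim(mask@voxels)))
  RNifti::pixdim(img) <- mask@spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Write an FD map as NIfTI (float32)
#'
#' @param fdmap An [FDMap-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFDMap <- function(fdmap, path) {
  stopifnot(methods::is(fdmap, "FDMap"))
  writeVolume(fdmap@values, fdmap@spacing, path)
}

#' Default pipeline configuration
#'
#' @return Named list: `targetSpacingMm` (0.7), `medianRadius` (2),
#'   `bilateralDistance` (1), `bilateralRangeFactor` (2),
#'   `shiftSearchRadius` (10), `windowRadius` (3), `localScales` (1:3),
#'   `seed` (1).
#' @export
defaultConfig <- function() {
  list(targetSpacingMm = 0.7, medianRadius = 2L, bilateralDistance = 1,
       bilateralRangeFactor = 2, shiftSearchRadius = 10L,
       windowRadius = 3L, localScales = 1:3, seed = 1L)
}

#' Read a JSON configuration, filling unset keys with defaults
#'
#' @param path JSON file path, or `NULL` for pure defaults.
#' @return Config list as in [defaultConfig()].
#' @export
readConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) stop("unknown config keys: ",
                              paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  cfg
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical (sorted-key) JSON serialization; embedded in every
#' output artefact so reruns are attributable to their exact parameters.
#'
#' @param config Config list.
#' @return Hex digest string.
#' @export
configHash <- function(config) {
  config <- config[order(names(config))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
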