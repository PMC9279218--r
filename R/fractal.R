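#' @include AllClasses.R AllGenerics.R
NULL

.as4d <- function(texture) {
  if (methods::is(texture, "PhaseStack")) texture <- voxels(texture)
  texture <- as.array(texture)
  if (length(dim(texture)) == 3L) dim(texture) <- c(dim(texture), 1L)
  if (length(dim(texture)) != 4L) stop("texture must be a 4D array")
  if (any(!is.finite(texture))) stop("texture contains non-finite values")
  storage.mode(texture) <- "double"
  texture
}

#' Iterate the upper and lower blankets of a 4D texture
#'
#' The two blankets are moulded to the intensity graph and iteratively
#' raised (upper) or lowered (lower) away from it: at every step the upper
#' blanket becomes the maximum of itself plus one and its 8 direct 4D
#' neighbours (one step along a single axis, the phase axis counting as a
#' full fourth dimension); the lower blanket is the mirrored minimum.
#' Boundaries are mirror-padded on all four axes. Loss of texture detail
#' with growing scale carries the fractal information.
#'
#' Intended for inspection and small oracle computations; [globalFD()] and
#' [localFDMap()] run the same iteration without materializing blankets.
#'
#' @param texture 4D numeric array or [PhaseStack-class]; 3D input is
#'   treated as a single-phase 4D texture.
#' @param maxEpsilon Number of iterations (>= 1).
#' @return List of length `maxEpsilon`; element `e` is a
#'   `list(upper=, lower=, epsilon=e)` of 4D arrays after `e` iterations.
#' @examples
#' p <- blanketIterate(array(7, c(3, 3, 3, 2)), 2)
#' stopifnot(all(p[[2]]$upper == 9), all(p[[2]]$lower == 5))
#' @export
blanketIterate <- function(texture, maxEpsilon) {
  texture <- .as4d(texture)
  maxEpsilon <- as.integer(maxEpsilon)
  if (maxEpsilon < 1L) stop("maxEpsilon must be >= 1")
  d <- dim(texture)
  raw <- cpp_blanket_pairs(as.numeric(texture), as.integer(d), maxEpsilon)
  lapply(seq_len(maxEpsilon), function(e) {
    list(upper = array(raw[[e]]$upper, d),
         lower = array(raw[[e]]$lower, d),
         epsilon = e)
  })
}

#' Inter-blanket surface measure per scale
#'
#' For each scale the measure is the incremental inter-blanket volume,
#' `A(e) = (V(e) - V(e-1)) / 2` with `V(e) = sum(upper - lower)` over the
#' evaluation region (all phases of the ROI voxels) and `V(0) = 0`,
#' averaged over phases. On a flat texture every scale yields exactly the
#' region's voxel count.
#'
#' @param pairs Blanket sequence from [blanketIterate()].
#' @param roi Optional [RegionMask-class] or 3D logical array restricting
#'   the spatial evaluation region (default whole grid).
#' @return data.frame with columns `epsilon` and `area`.
#' @export
surfaceMeasure <- function(pairs, roi = NULL) {
  if (length(pairs) < 1L) stop("empty blanket sequence")
  d <- dim(pairs[[1]]$upper)
  np <- d[4]
  sel <- if (is.null(roi)) NULL else {
    m <- if (methods::is(roi, "RegionMask")) voxels(roi) else roi
    if (!all(dim(m) == d[1:3])) stop("ROI grid does not match blanket grid")
    which(m)
  }
  V <- vapply(pairs, function(p) {
    diff <- p$upper - p$lower
    if (is.null(sel)) sum(diff)
    else sum(vapply(seq_len(np), function(q) sum(diff[, , , q][sel]),
                    numeric(1)))
  }, numeric(1))
  data.frame(epsilon = vapply(pairs, `[[`, integer(1), "epsilon"),
             area = diff(c(0, V)) / 2 / np)
}

#' Fit a fractal dimension to surface measures
#'
#' Least-squares regression of `log(area)` on `log(scale)`; the FD is the
#' support dimension minus the slope, clamped into
#' `[supportDim, supportDim + 1]` (discretization can push the raw slope
#' slightly past the theoretical bounds). A constant area sequence is the
#' flat-texture limit: slope 0, FD equal to the support dimension, and the
#' degenerate zero-variance fit is reported as perfect (R2 = 1).
#'
#' @param scales Integer blanket scales (>= 2 distinct values).
#' @param areas Positive surface measures, same length.
#' @param supportDim Dimension of the texture support (4 for the
#'   three-spatial-plus-phase application).
#' @return List with `fd`, `slope`, `r2`, `clamped`, `logScales`, `logAreas`.
#' @export
fitFD <- function(scales, areas, supportDim = 4) {
  if (length(scales) != length(areas)) stop("scales/areas length mismatch")
  if (length(unique(scales)) < 2L) stop("need >= 2 distinct scales")
  if (any(areas <= 0)) stop("surface measures must be positive")
  lx <- log(as.numeric(scales))
  ly <- log(as.numeric(areas))
  fit <- stats::lm(ly ~ lx)
  slope <- unname(stats::coef(fit)[2])
  if (max(ly) - min(ly) < 1e-14) slope <- 0  # flat-texture limit, exactly
  ssTot <- sum((ly - mean(ly))^2)
  r2 <- if (ssTot < 1e-24) 1 else max(0, min(1, 1 - sum(stats::resid(fit)^2) / ssTot))
  fd <- supportDim - slope
  clamped <- fd < supportDim || fd > supportDim + 1
  fd <- min(max(fd, supportDim), supportDim + 1)
  list(fd = fd, slope = slope, r2 = r2, clamped = clamped,
       logScales = lx, logAreas = ly)
}

.defaultGlobalScales <- function(roiVox) {
  idx <- which(roiVox, arr.ind = TRUE)
  ext <- apply(idx, 2, function(i) diff(range(i)) + 1L)
  maxeps <- max(2L, min(4L, floor(min(ext) / 2)))
  seq_len(maxeps)
}

#' Global fractal dimension of a region of interest
#'
#' Blankets are iterated over the full 4D stack and the surface measure is
#' accumulated over the ROI voxels only (all phases), yielding one FD
#' scalar that summarizes the perfusion chaos of an anatomically coherent
#' region such as the tumour core, tumour rim or remote pancreas.
#'
#' @param stack [PhaseStack-class] (normalized input is the intended use)
#'   or 4D array.
#' @param roi [RegionMask-class] or 3D logical array, non-empty.
#' @param scales Integer blanket scales; default `1:min(4, e/2)` where `e`
#'   is the smallest bounding-box extent of the ROI, keeping the regression
#'   inside the texture-dominated regime (larger scales mostly measure the
#'   blanket's reach into neighbouring structures and intensity edges).
#' @param centerPhases Subtract each phase's mean over the ROI before the
#'   blanket iteration (default `TRUE`). The portal-vein normalization puts
#'   all phases on one scale but leaves each tissue with a different bulk
#'   enhancement level per phase; along the phase axis the blanket would
#'   read those level steps as a cliff at every voxel and drown the texture
#'   signal. Centring makes the FD a measure of the enhancement *pattern*
#'   (perfusion chaos) rather than of the enhancement kinetics themselves.
#' @return A [GlobalFDResult-class].
#' @export
globalFD <- function(stack, roi, scales = NULL, centerPhases = TRUE) {
  tex <- .as4d(stack)
  d <- dim(tex)
  label <- if (methods::is(roi, "RegionMask")) maskLabel(roi) else "roi"
  m <- if (methods::is(roi, "RegionMask")) voxels(roi) else as.array(roi)
  if (!all(dim(m) == d[1:3])) stop("ROI grid does not match stack grid")
  if (!any(m)) stop("empty ROI")
  if (is.null(scales)) scales <- .defaultGlobalScales(m)
  scales <- sort(unique(as.integer(scales)))
  if (length(scales) < 2L) stop("need >= 2 scales")
  if (centerPhases) {
    sel <- which(m)
    for (p in seq_len(d[4]))
      tex[, , , p] <- tex[, , , p] - mean(tex[, , , p][sel])
  }
  V <- cpp_blanket_volumes(as.numeric(tex), as.integer(d), max(scales),
                           as.logical(m))
  A <- (diff(c(0, V)) / 2 / d[4])[scales]
  fit <- fitFD(scales, A, supportDim = 4)
  methods::new("GlobalFDResult", fd = fit$fd, logScales = fit$logScales,
               logAreas = fit$logAreas, fitR2 = fit$r2,
               clamped = fit$clamped, roiLabel = label)
}

#' Local fractal dimension map
#'
#' For every spatial voxel the blanket analysis runs inside the voxel's
#' immediate 4D vicinity: a window of half-width `windowRadius` voxels,
#' mirror-padded at volume boundaries and across the phase axis, so each
#' voxel receives the FD of its own neighbourhood texture. Values are
#' clamped into `[4, 5]` and the clipped fraction is reported.
#'
#' @param stack [PhaseStack-class] (normalized input is the intended use)
#'   or 4D array.
#' @param windowRadius Window half-width in voxels (default 3); must be at
#'   least `max(scales)`.
#' @param scales Integer blanket scales for the per-window fit (default
#'   `1:3`).
#' @param centerPhases Subtract each phase's mean over the local window
#'   before the blanket iteration (default `TRUE`); see [globalFD()] for
#'   the rationale.
#' @return An [FDMap-class] on the stack's spatial grid.
#' @export
localFDMap <- function(stack, windowRadius = 3L, scales = 1:3,
                       centerPhases = TRUE) {
  tex <- .as4d(stack)
  spacing <- if (methods::is(stack, "PhaseStack")) voxelSpacing(stack)
    else c(1, 1, 1)
  scales <- sort(unique(as.integer(scales)))
  if (length(scales) < 2L) stop("need >= 2 scales")
  windowRadius <- as.integer(windowRadius)
  if (windowRadius < max(scales))
    stop("windowRadius must be >= max(scales)")
  d <- dim(tex)
  res <- cpp_local_fd(as.numeric(tex), as.integer(d), windowRadius, scales,
                      centerPhases)
  vals <- array(res$map, d[1:3])
  methods::new("FDMap", values = vals, spacing = as.numeric(spacing),
               clampedFraction = res$clamped / prod(d[1:3]),
               scalesUsed = scales)
}
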