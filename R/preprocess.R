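#' @include AllClasses.R AllGenerics.R
NULL

.checkSameGrid <- function(stack, mask) {
  if (!all(dim(stack)[1:3] == dim(mask)))
    stop("mask grid ", paste(dim(mask), collapse = "x"),
         " does not match stack grid ",
         paste(dim(stack)[1:3], collapse = "x"))
  if (max(abs(voxelSpacing(stack) - voxelSpacing(mask))) > 1e-4)
    stop("mask spacing does not match stack spacing")
  invisible(TRUE)
}

.resolvePhase <- function(stack, phase) {
  if (is.character(phase)) {
    i <- match(phase, phaseLabels(stack))
    if (is.na(i)) stop("unknown phase label: ", phase)
    return(i)
  }
  phase <- as.integer(phase)
  if (phase < 1L || phase > dim(stack)[4]) stop("phase index out of range")
  phase
}

#' @rdname resampleIsotropic
#' @export
setMethod("resampleIsotropic", "PhaseStack", function(x, targetMm = 0.7) {
  if (!is.numeric(targetMm) || length(targetMm) != 1L || targetMm <= 0)
    stop("targetMm must be a positive scalar")
  d <- dim(x@voxels)
  if (any(d[1:3] < 1L)) stop("empty grid")
  odims <- pmax(1L, as.integer(round(d[1:3] * x@spacing / targetMm)))
  out <- array(0, c(odims, d[4]))
  for (p in seq_len(d[4])) {
    out[, , , p] <- array(
      cpp_resample3d(as.numeric(x@voxels[, , , p]), as.integer(d[1:3]),
                     x@spacing, rep(targetMm, 3), odims, FALSE),
      odims)
  }
  methods::new("PhaseStack", voxels = out, spacing = rep(targetMm, 3),
               phaseLabels = x@phaseLabels, normalized = x@normalized)
})

#' @rdname resampleIsotropic
#' @export
setMethod("resampleIsotropic", "RegionMask", function(x, targetMm = 0.7) {
  if (!is.numeric(targetMm) || length(targetMm) != 1L || targetMm <= 0)
    stop("targetMm must be a positive scalar")
  d <- dim(x@voxels)
  odims <- pmax(1L, as.integer(round(d * x@spacing / targetMm)))
  v <- cpp_resample3d(as.numeric(x@voxels), as.integer(d), x@spacing,
                      rep(targetMm, 3), odims, TRUE)
  RegionMask(array(v > 0.5, odims), rep(targetMm, 3), x@label)
})

#' Estimate image noise from a muscle ROI
#'
#' The standard deviation of Hounsfield units inside a region placed in the
#' spinal erector muscles serves as the scanner noise level that the
#' bilateral filter's range parameter is tied to.
#'
#' @param stack A [PhaseStack-class].
#' @param muscleRoi [RegionMask-class] on the same grid, >= 2 voxels.
#' @param phase Phase index or label to measure in (default first phase).
#' @return A [NoiseEstimate-class].
#' @export
estimateNoise <- function(stack, muscleRoi, phase = 1L) {
  .checkSameGrid(stack, muscleRoi)
  p <- .resolvePhase(stack, phase)
  vals <- stack@voxels[, , , p][muscleRoi@voxels]
  if (length(vals) < 2L) stop("noise ROI must contain at least 2 voxels")
  methods::new("NoiseEstimate", sdHU = stats::sd(vals),
               roiVoxelCount = length(vals))
}

#' Noise-adaptive denoising of a multiphasic stack
#'
#' Each phase is filtered independently with a 3D median filter (radius 2
#' voxels) followed by a 3D bilateral filter (spatial parameter 1 voxel;
#' range parameter `bilateralRangeFactor * sdHU`, tying the photometric
#' scale to the measured noise floor). Mirror padding avoids edge darkening
#' that would bias FD estimates at the volume border. The grid is unchanged,
#' and constant volumes pass through exactly.
#'
#' @param stack A [PhaseStack-class].
#' @param noise A [NoiseEstimate-class] (see [estimateNoise()]).
#' @param medianRadius Median half-width in voxels (default 2).
#' @param bilateralDistance Spatial Gaussian sd of the bilateral filter in
#'   voxels (default 1).
#' @param bilateralRangeFactor Multiplier applied to `sdHU` to obtain the
#'   bilateral range sd (default 2).
#' @return A denoised [PhaseStack-class] on the identical grid.
#' @export
denoiseStack <- function(stack, noise, medianRadius = 2L,
                         bilateralDistance = 1, bilateralRangeFactor = 2) {
  stopifnot(methods::is(stack, "PhaseStack"), methods::is(noise, "NoiseEstimate"))
  d <- dim(stack@voxels)
  out <- stack@voxels
  rangeSigma <- bilateralRangeFactor * noise@sdHU
  bilRadius <- max(1L, as.integer(ceiling(2 * bilateralDistance)))
  for (p in seq_len(d[4])) {
    v <- as.numeric(out[, , , p])
    v <- cpp_median3d(v, as.integer(d[1:3]), as.integer(medianRadius))
    if (rangeSigma > 0)
      v <- cpp_bilateral3d(v, as.integer(d[1:3]), bilateralDistance,
                           rangeSigma, bilRadius)
    out[, , , p] <- v
  }
  methods::new("PhaseStack", voxels = out, spacing = stack@spacing,
               phaseLabels = stack@phaseLabels, normalized = stack@normalized)
}

#' Measure portal-vein reference signals
#'
#' Reduces the portal-vein ROI to its mean intensity per phase: `i0` from
#' the unenhanced phase and one `ipv` entry per contrast phase.
#'
#' @param stack A [PhaseStack-class] in HU.
#' @param veinMask Portal-vein [RegionMask-class] on the stack grid.
#' @param unenhancedPhase Label or index of the unenhanced phase.
#' @return A [ReferenceSignals-class].
#' @export
measureReferenceSignals <- function(stack, veinMask,
                                    unenhancedPhase = "unenhanced") {
  .checkSameGrid(stack, veinMask)
  if (sum(veinMask@voxels) < 1L) stop("empty portal-vein mask")
  p0 <- .resolvePhase(stack, unenhancedPhase)
  labs <- phaseLabels(stack)
  means <- vapply(seq_along(labs),
                  function(p) mean(stack@voxels[, , , p][veinMask@voxels]),
                  numeric(1))
  ipv <- means[-p0]
  names(ipv) <- labs[-p0]
  ReferenceSignals(i0 = means[p0], ipv = ipv)
}

#' Portal-vein intensity normalization
#'
#' Rescales every contrast phase to
#' `I = (I_voxel - I0) / (I_pv - I0) * 100`, so 0 corresponds to the
#' unenhanced portal-vein signal and 100 to the portal-vein signal of the
#' respective phase. The unenhanced phase has no portal-vein enhancement of
#' its own (the formula's denominator would vanish), so it is mapped with
#' the denominator of the phase named by `unenhancedDenominator`, putting
#' the whole stack on one intensity scale.
#'
#' @param stack A [PhaseStack-class] in HU, not yet normalized.
#' @param refs A [ReferenceSignals-class].
#' @param unenhancedDenominator Contrast-phase label whose denominator maps
#'   the unenhanced phase (default the portal-venous phase when present,
#'   otherwise the last contrast phase).
#' @return A normalized [PhaseStack-class] (`isNormalized(.) == TRUE`).
#' @export
normalizeEnhancement <- function(stack, refs, unenhancedDenominator = NULL) {
  stopifnot(methods::is(stack, "PhaseStack"),
            methods::is(refs, "ReferenceSignals"))
  if (stack@normalized) stop("stack is already normalized")
  labs <- phaseLabels(stack)
  ipv <- refs@ipv
  if (is.null(unenhancedDenominator))
    unenhancedDenominator <- if ("portal_venous" %in% names(ipv))
      "portal_venous" else names(ipv)[length(ipv)]
  if (!unenhancedDenominator %in% names(ipv))
    stop("unenhancedDenominator must name a contrast phase with an ipv entry")
  out <- stack@voxels
  for (p in seq_along(labs)) {
    ref <- if (labs[p] %in% names(ipv)) ipv[labs[p]] else ipv[unenhancedDenominator]
    denom <- ref - refs@i0
    if (abs(denom) < 1e-9) stop("zero denominator for phase ", labs[p])
    out[, , , p] <- (stack@voxels[, , , p] - refs@i0) / denom * 100
  }
  methods::new("PhaseStack", voxels = out, spacing = stack@spacing,
               phaseLabels = labs, normalized = TRUE)
}

.fftShiftGrid <- function(n) {
  # shift value corresponding to each index of the cross-correlation array
  s <- seq_len(n) - 1L
  s[s > n %/% 2] <- s[s > n %/% 2] - n
  s
}

.gradMag <- function(vol) {
  # central-difference gradient magnitude; contrast-polarity-free feature
  # image for cross-phase alignment (tissue contrast inverts between
  # unenhanced and enhanced phases, raw intensity correlation does not)
  d <- dim(vol)
  g2 <- array(0, d)
  for (ax in 1:3) {
    lo <- lapply(d, seq_len); hi <- lo
    lo[[ax]] <- pmax(seq_len(d[ax]) - 1L, 1L)
    hi[[ax]] <- pmin(seq_len(d[ax]) + 1L, d[ax])
    g2 <- g2 + (do.call(`[`, c(list(vol), hi)) -
                do.call(`[`, c(list(vol), lo)))^2
  }
  sqrt(g2)
}

.applyShift <- function(vol, shift) {
  # translate content by `shift` voxels; exposed regions take the edge value
  d <- dim(vol)
  idx <- lapply(1:3, function(a) pmin(pmax(seq_len(d[a]) - shift[a], 1L), d[a]))
  vol[idx[[1]], idx[[2]], idx[[3]]]
}

#' Rigid integer-shift phase alignment
#'
#' A deliberately minimal alignment fallback for stacks that are already
#' approximately co-registered: each non-reference phase is translated by
#' the integer voxel shift (within `searchRadius` per axis) that maximizes
#' the FFT cross-correlation of its gradient-magnitude image with the
#' reference phase's. Gradient magnitudes are used because tissue contrast
#' inverts between unenhanced and contrast-enhanced phases, which would
#' defeat raw intensity correlation; edges stay put. Deformable or
#' sub-voxel registration is out of scope; stacks registered externally
#' pass through unchanged (zero shifts).
#'
#' @param stack A [PhaseStack-class].
#' @param referencePhase Index or label of the reference phase (default the
#'   portal-venous phase when present, otherwise the last phase).
#' @param searchRadius Maximum absolute shift per axis in voxels (default 10).
#' @param minCorrelation Normalized-correlation threshold below which the
#'   shift is flagged low-confidence (default 0.3).
#' @return A list with `stack` (aligned [PhaseStack-class]) and `report`
#'   (data.frame: phase, shift_x/y/z, correlation, low_confidence).
#' @export
alignPhases <- function(stack, referencePhase = NULL, searchRadius = 10L,
                        minCorrelation = 0.3) {
  stopifnot(methods::is(stack, "PhaseStack"))
  labs <- phaseLabels(stack)
  if (is.null(referencePhase))
    referencePhase <- if ("portal_venous" %in% labs) "portal_venous"
      else length(labs)
  pref <- .resolvePhase(stack, referencePhase)
  d <- dim(stack@voxels)[1:3]
  ref <- .gradMag(stack@voxels[, , , pref])
  refC <- ref - mean(ref)
  sdRef <- sqrt(sum(refC^2))
  fref <- stats::fft(refC)
  shifts <- lapply(d, .fftShiftGrid)
  win <- lapply(seq_along(d),
                function(a) abs(shifts[[a]]) <= min(searchRadius, d[a] %/% 2))
  out <- stack@voxels
  rep_list <- vector("list", length(labs))
  for (p in seq_along(labs)) {
    if (p == pref) {
      rep_list[[p]] <- data.frame(phase = labs[p], shift_x = 0L, shift_y = 0L,
                                  shift_z = 0L, correlation = 1,
                                  low_confidence = FALSE)
      next
    }
    mov <- stack@voxels[, , , p]
    movG <- .gradMag(mov)
    movC <- movG - mean(movG)
    sdMov <- sqrt(sum(movC^2))
    if (sdRef < 1e-12 || sdMov < 1e-12) {
      rep_list[[p]] <- data.frame(phase = labs[p], shift_x = 0L, shift_y = 0L,
                                  shift_z = 0L, correlation = 0,
                                  low_confidence = TRUE)
      next
    }
    cc <- Re(stats::fft(fref * Conj(stats::fft(movC)), inverse = TRUE)) /
      prod(d) / (sdRef * sdMov)
    cc[!win[[1]], , ] <- -Inf
    cc[, !win[[2]], ] <- -Inf
    cc[, , !win[[3]]] <- -Inf
    k <- arrayInd(which.max(cc), d)
    # cc peaks at k = -t when the moving phase content is displaced by t
    sh <- -c(shifts[[1]][k[1]], shifts[[2]][k[2]], shifts[[3]][k[3]])
    corr <- max(cc)
    low <- corr < minCorrelation
    if (!low && any(sh != 0L)) out[, , , p] <- .applyShift(mov, -sh)
    rep_list[[p]] <- data.frame(phase = labs[p], shift_x = sh[1],
                                shift_y = sh[2], shift_z = sh[3],
                                correlation = corr, low_confidence = low)
  }
  aligned <- methods::new("PhaseStack", voxels = out, spacing = stack@spacing,
                          phaseLabels = labs, normalized = stack@normalized)
  list(stack = aligned, report = do.call(rbind, rep_list))
}
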