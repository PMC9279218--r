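mkStack <- function(arr, spacing = c(1, 1, 1), labels = NULL)
  PhaseStack(arr, spacing, labels)

test_that("isotropic resampling preserves extent and handles identity", {
  set.seed(1)
  s <- mkStack(array(rnorm(12 * 14 * 100 * 2), c(12, 14, 100, 2)),
               c(0.7, 0.7, 1.25))
  r <- resampleIsotropic(s, 0.7)
  expect_equal(dim(r)[3], 179L)            # 100 * 1.25 / 0.7, extent kept
  expect_equal(dim(r)[1:2], c(12L, 14L))
  expect_equal(voxelSpacing(r), rep(0.7, 3))

  iso <- mkStack(array(rnorm(8^3 * 2), c(8, 8, 8, 2)), rep(0.7, 3))
  expect_equal(voxels(resampleIsotropic(iso, 0.7)), voxels(iso),
               tolerance = 1e-12)

  const <- mkStack(array(7, c(6, 6, 20, 2)), c(1, 1, 2.5))
  rc <- resampleIsotropic(const, 1)
  expect_true(all(abs(voxels(rc) - 7) < 1e-9))

  expect_error(resampleIsotropic(s, -1), "positive")
})

test_that("resampling at the same target is idempotent", {
  g <- seq(0, 40, length.out = 16)
  vol <- outer(outer(g, g, `+`), g, `+`)
  smooth <- array(rep(vol, 2), c(16, 16, 16, 2))
  s <- mkStack(smooth, rep(0.9, 3))
  r1 <- resampleIsotropic(s, 0.7)
  r2 <- resampleIsotropic(r1, 0.7)
  expect_identical(dim(r1), dim(r2))
  expect_lt(max(abs(voxels(r1) - voxels(r2))), 1)
})

test_that("mask resampling is nearest-neighbour and label-preserving", {
  m <- RegionMask(array(rep(c(TRUE, FALSE), 50), c(10, 10, 1)),
                  c(1, 1, 5), "core")
  r <- resampleIsotropic(m, 1)
  expect_true(is.logical(voxels(r)))
  expect_identical(maskLabel(r), "core")
  expect_identical(sort(unique(as.vector(voxels(r)))), c(FALSE, TRUE))
})

test_that("noise estimation matches the ROI standard deviation", {
  arr <- array(100, c(10, 10, 10, 2))
  roi <- array(FALSE, c(10, 10, 10)); roi[1:5, 1, 1] <- TRUE
  s <- mkStack(arr)
  expect_equal(estimateNoise(s, RegionMask(roi, c(1, 1, 1)))@sdHU, 0)

  arr[1:10, 1, 1, 1] <- rep(c(9, 11), 5)
  roi2 <- array(FALSE, c(10, 10, 10)); roi2[1:10, 1, 1] <- TRUE
  n <- estimateNoise(mkStack(arr), RegionMask(roi2, c(1, 1, 1)), phase = 1)
  expect_equal(n@sdHU, 1, tolerance = 0.06)
  expect_identical(n@roiVoxelCount, 10L)

  set.seed(42)
  big <- array(rnorm(22^3 * 2, sd = 10), c(22, 22, 22, 2))
  roi3 <- array(TRUE, c(22, 22, 22))       # 10648 voxels
  nb <- estimateNoise(mkStack(big), RegionMask(roi3, c(1, 1, 1)))
  expect_equal(nb@sdHU, 10, tolerance = 0.5)

  tiny <- array(FALSE, c(10, 10, 10)); tiny[1, 1, 1] <- TRUE
  expect_error(estimateNoise(s, RegionMask(tiny, c(1, 1, 1))), "2 voxels")
})

test_that("denoising preserves constants, kills impulses, reduces noise", {
  noise <- methods::new("NoiseEstimate", sdHU = 10, roiVoxelCount = 100L)
  const <- mkStack(array(5, c(12, 12, 12, 2)))
  expect_identical(voxels(denoiseStack(const, noise)), voxels(const))

  imp <- array(0, c(12, 12, 12, 2)); imp[6, 6, 6, 1] <- 1000
  d <- denoiseStack(mkStack(imp), noise)
  expect_equal(voxels(d)[6, 6, 6, 1], 0, tolerance = 1e-9)
  expect_identical(dim(d), c(12L, 12L, 12L, 2L))

  set.seed(3)
  noisy <- array(100 + rnorm(16^3 * 2, sd = 20), c(16, 16, 16, 2))
  dn <- denoiseStack(mkStack(noisy),
                     methods::new("NoiseEstimate", sdHU = 20,
                                  roiVoxelCount = 100L))
  expect_lt(sd(voxels(dn)), sd(noisy))
})

test_that("portal-vein normalization maps the reference points to 0/50/100", {
  arr <- array(0, c(4, 4, 4, 3))
  arr[, , , 1] <- 50; arr[, , , 2] <- 105; arr[, , , 3] <- 160
  arr[1, 1, 1, 2] <- 160; arr[2, 1, 1, 2] <- 50
  s <- mkStack(arr)
  refs <- ReferenceSignals(50, c(parenchymal = 160, portal_venous = 200))
  n <- normalizeEnhancement(s, refs)
  expect_true(isNormalized(n))
  expect_equal(voxels(n)[1, 1, 1, 2], 100)   # I_voxel = ipv -> 100
  expect_equal(voxels(n)[2, 1, 1, 2], 0)     # I_voxel = i0 -> 0
  expect_equal(voxels(n)[3, 1, 1, 2], 50)    # midpoint -> 50
  # unenhanced phase shares the portal-venous denominator
  expect_equal(voxels(n)[1, 1, 1, 1], 0)
  expect_error(normalizeEnhancement(n, refs), "already")
})

test_that("normalization is affine per phase (correlation exactly 1)", {
  set.seed(4)
  arr <- array(rnorm(6^3 * 3, mean = 100, sd = 20), c(6, 6, 6, 3))
  s <- mkStack(arr)
  refs <- ReferenceSignals(40, c(parenchymal = 150, portal_venous = 190))
  n <- normalizeEnhancement(s, refs)
  for (p in 1:3)
    expect_equal(cor(as.vector(arr[, , , p]), as.vector(voxels(n)[, , , p])),
                 1, tolerance = 1e-12)
})

test_that("vein-mean measurement plus normalization puts the vein at 100", {
  set.seed(5)
  arr <- array(rnorm(10^3 * 3, 60, 4), c(10, 10, 10, 3))
  vein <- array(FALSE, c(10, 10, 10)); vein[4:6, 4:6, ] <- TRUE
  arr[, , , 2][vein] <- rnorm(sum(vein), 150, 4)
  arr[, , , 3][vein] <- rnorm(sum(vein), 200, 4)
  s <- mkStack(arr)
  refs <- measureReferenceSignals(s, RegionMask(vein, c(1, 1, 1), "portal_vein"))
  n <- normalizeEnhancement(s, refs)
  for (p in 2:3)
    expect_equal(mean(voxels(n)[, , , p][vein]), 100, tolerance = 1e-9)
})

test_that("phase alignment recovers constructed integer shifts exactly", {
  set.seed(6)
  base <- array(rnorm(24^3), c(24, 24, 24))
  for (i in 1:2)
    base <- (base + base[c(1, 1:23), , ] + base[, c(1, 1:23), ] +
             base[, , c(1, 1:23)]) / 4
  idx <- function(n, s) pmin(pmax(seq_len(n) + s, 1), n)
  mov <- base[idx(24, 2), idx(24, -1), idx(24, 0)]  # content moved (-2, +1, 0)
  s <- mkStack(array(c(base, mov), c(24, 24, 24, 2)), labels = c("a", "b"))
  al <- alignPhases(s, referencePhase = 1)
  expect_equal(unlist(al$report[2, c("shift_x", "shift_y", "shift_z")]),
               c(shift_x = -2, shift_y = 1, shift_z = 0))
  expect_false(al$report$low_confidence[2])

  ident <- mkStack(array(rep(base, 2), c(24, 24, 24, 2)))
  ri <- alignPhases(ident, referencePhase = 1)$report
  expect_true(all(ri[, c("shift_x", "shift_y", "shift_z")] == 0))
})

test_that("degenerate or uncorrelated phases are flagged low-confidence", {
  set.seed(7)
  a <- array(rnorm(16^3), c(16, 16, 16))
  b <- array(rnorm(16^3), c(16, 16, 16))
  s <- mkStack(array(c(a, b), c(16, 16, 16, 2)))
  expect_true(alignPhases(s, referencePhase = 1)$report$low_confidence[2])

  flat <- mkStack(array(c(a, rep(0, 16^3)), c(16, 16, 16, 2)))
  rep2 <- alignPhases(flat, referencePhase = 1)$report
  expect_true(rep2$low_confidence[2])
  expect_true(all(rep2[2, c("shift_x", "shift_y", "shift_z")] == 0))
})
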