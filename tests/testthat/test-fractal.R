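test_that("blankets of a flat texture move by exactly one per scale", {
  p <- blanketIterate(array(3, c(4, 4, 4, 2)), 3)
  for (e in 1:3) {
    expect_true(all(p[[e]]$upper == 3 + e))
    expect_true(all(p[[e]]$lower == 3 - e))
  }
  sm <- surfaceMeasure(p)
  expect_equal(sm$area, rep(64, 3))   # scale-independent, equals voxel count
})

test_that("a single impulse spreads to its 8 direct 4D neighbours at eps 1", {
  tex <- array(0, c(3, 3, 3, 3))
  tex[2, 2, 2, 2] <- 10
  u1 <- blanketIterate(tex, 1)[[1]]$upper
  raised <- which(u1 == 10, arr.ind = TRUE)
  expect_identical(nrow(raised), 8L)     # one step along a single axis
  expect_equal(sum(abs(sweep(raised, 2, c(2, 2, 2, 2)))), 8)
  expect_equal(u1[2, 2, 2, 2], 11)       # impulse itself raised by +1
})

test_that("blanket sandwich and monotonicity hold on random textures", {
  set.seed(11)
  tex <- array(rnorm(5 * 5 * 5 * 3, sd = 5), c(5, 5, 5, 3))
  p <- blanketIterate(tex, 3)
  expect_true(all(p[[1]]$upper >= tex), label = "upper above texture")
  expect_true(all(p[[1]]$lower <= tex), label = "lower below texture")
  for (e in 2:3) {
    expect_true(all(p[[e]]$upper >= p[[e - 1]]$upper))
    expect_true(all(p[[e]]$lower <= p[[e - 1]]$lower))
  }
})

test_that("blanket iteration matches the naive reference implementation", {
  set.seed(12)
  tex <- array(rnorm(4 * 5 * 3 * 2, sd = 3), c(4, 5, 3, 2))
  p <- blanketIterate(tex, 3)
  u <- tex; b <- tex
  for (e in 1:3) {
    u <- oracleBlanketStep(u, TRUE)
    b <- oracleBlanketStep(b, FALSE)
    expect_equal(p[[e]]$upper, u)
    expect_equal(p[[e]]$lower, b)
  }
})

test_that("checkerboard surface measure agrees with brute-force evaluation", {
  tex <- array(0, c(2, 2, 2, 2))
  tex[] <- (slice.index(tex, 1) + slice.index(tex, 2) +
            slice.index(tex, 3) + slice.index(tex, 4)) %% 2
  sm <- surfaceMeasure(blanketIterate(tex, 2))
  V <- oracleBlanketVolumes(tex, 2)
  expect_equal(sm$area, diff(c(0, V)) / 2 / 2)
})

test_that("fitFD reproduces the closed-form limits and diagnostics", {
  flat <- fitFD(1:4, rep(100, 4))
  expect_equal(flat$fd, 4)
  expect_equal(flat$r2, 1)      # degenerate zero-variance fit
  expect_false(flat$clamped)

  chaos <- fitFD(1:4, 1000 / (1:4))
  expect_equal(chaos$fd, 5)

  over <- fitFD(1:4, 1000 / (1:4)^1.2)   # steeper than the power law allows
  expect_equal(over$fd, 5)
  expect_true(over$clamped)

  expect_error(fitFD(c(1, 1), c(2, 3)), "distinct")
  expect_error(fitFD(1:3, c(1, -1, 1)), "positive")
})

test_that("local FD map of a flat stack is exactly 4 with zero clamping", {
  m <- localFDMap(PhaseStack(array(9, c(8, 8, 8, 3)), c(1, 1, 1)))
  expect_true(all(voxels(m) == 4))
  expect_equal(clampedFraction(m), 0)
  expect_identical(scalesUsed(m), 1:3)
})

test_that("local FD maps stay inside [4, 5] on adversarial stacks", {
  set.seed(13)
  stacks <- list(
    array(rcauchy(10 * 10 * 6 * 3), c(10, 10, 6, 3)),
    array(sample(c(-1e6, 0, 1e6), 10 * 10 * 6 * 3, TRUE), c(10, 10, 6, 3)),
    array(runif(10 * 10 * 6 * 3, -1, 1), c(10, 10, 6, 3)))
  for (s in stacks) {
    m <- localFDMap(PhaseStack(s, c(1, 1, 1), paste0("p", 1:3)))
    expect_true(all(voxels(m) >= 4 & voxels(m) <= 5))
    expect_gte(clampedFraction(m), 0)
    expect_lte(clampedFraction(m), 1)
  }
})

test_that("a noisy region maps to higher local FD than flat surroundings", {
  set.seed(14)
  tex <- array(0, c(16, 16, 8, 3))
  noiseReg <- array(FALSE, c(16, 16, 8)); noiseReg[4:13, 4:13, 3:6] <- TRUE
  for (p in 1:3) {
    sl <- tex[, , , p]
    sl[noiseReg] <- runif(sum(noiseReg), -20, 20)
    tex[, , , p] <- sl
  }
  m <- voxels(localFDMap(PhaseStack(tex, c(1, 1, 1), paste0("p", 1:3))))
  inner <- dilate3(noiseReg, 3)
  expect_gt(mean(m[noiseReg]), mean(m[!inner]))
})

test_that("local FD map equals the naive per-window implementation exactly", {
  for (seed in 1:3) {
    set.seed(seed)
    tex <- array(rnorm(5 * 5 * 5 * 3, sd = 8), c(5, 5, 5, 3))
    fast <- voxels(localFDMap(PhaseStack(tex, c(1, 1, 1), paste0("p", 1:3)),
                              windowRadius = 3L, scales = 1:3))
    naive <- oracleLocalFD(tex, 3L, 1:3)
    expect_equal(fast, naive, tolerance = 1e-12)
  }
})

test_that("FD is invariant under a constant gray shift", {
  set.seed(15)
  tex <- array(rnorm(8 * 8 * 6 * 3, sd = 10), c(8, 8, 6, 3))
  roi <- array(TRUE, c(8, 8, 6))
  s1 <- PhaseStack(tex, c(1, 1, 1), paste0("p", 1:3))
  s2 <- PhaseStack(tex + 137.5, c(1, 1, 1), paste0("p", 1:3))

  # the blanket itself commutes with gray shifts exactly
  a1 <- surfaceMeasure(blanketIterate(tex, 3))
  a2 <- surfaceMeasure(blanketIterate(tex + 137.5, 3))
  expect_identical(fitFD(a1$epsilon, a1$area)$fd,
                   fitFD(a2$epsilon, a2$area)$fd)

  # the centred map/global estimators are shift-invariant to rounding
  expect_equal(voxels(localFDMap(s1)), voxels(localFDMap(s2)),
               tolerance = 1e-9)
  expect_equal(globalFD(s1, roi)@fd, globalFD(s2, roi)@fd,
               tolerance = 1e-9)
})

test_that("global FD of a flat ROI is 4 with a perfect degenerate fit", {
  roi <- array(FALSE, c(8, 8, 8)); roi[2:6, 3:5, 2:7] <- TRUE
  g <- globalFD(array(5, c(8, 8, 8, 3)), roi, scales = 1:3)
  expect_equal(g@fd, 4)
  expect_equal(g@fitR2, 1)
  expect_equal(exp(g@logAreas)[1], sum(roi))  # first-scale measure = n
  expect_error(globalFD(array(5, c(8, 8, 8, 3)), array(FALSE, c(8, 8, 8))),
               "empty")
})

test_that("global FD recovers the fBm graph dimension", {
  f <- 50 * fbmField(c(32, 32, 32, 8), hurst = 0.5, seed = 3)
  g <- globalFD(f, array(TRUE, c(32, 32, 32)))
  expect_equal(g@fd, 4.5, tolerance = 0.15)
  expect_gt(g@fitR2, 0.9)
})

test_that("global FD responds monotonically to noise amplitude", {
  roi <- array(TRUE, c(16, 16, 12))
  inversions <- 0L
  for (seed in 1:5) {
    set.seed(seed)
    fds <- sapply(c(0, 5, 20), function(a)
      globalFD(array(100 + a * rnorm(16 * 16 * 12 * 3), c(16, 16, 12, 3)),
               roi)@fd)
    inversions <- inversions + sum(diff(fds) < 0)
  }
  expect_lte(inversions, 1L)
})
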