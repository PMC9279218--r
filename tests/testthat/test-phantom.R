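test_that("fBm fields are deterministic per seed and Hurst-consistent", {
  f1 <- fbmField(c(12, 12, 12), 0.5, seed = 7)
  f2 <- fbmField(c(12, 12, 12), 0.5, seed = 7)
  expect_identical(f1, f2)
  expect_false(identical(f1, fbmField(c(12, 12, 12), 0.5, seed = 8)))
  expect_error(fbmField(c(8, 8, 8), 1.2, 1), "between")

  # structure function: increment variance ~ r^(2H)
  f <- fbmField(c(64, 64, 64), 0.5, seed = 1)
  sf <- function(ax, r) {
    d <- dim(f); i1 <- lapply(d, seq_len); i2 <- i1
    i1[[ax]] <- seq_len(d[ax] - r); i2[[ax]] <- (r + 1):d[ax]
    mean((do.call(`[`, c(list(f), i2)) - do.call(`[`, c(list(f), i1)))^2)
  }
  v <- sapply(1:8, function(r) mean(sapply(1:3, sf, r = r)))
  slope <- unname(coef(lm(log(v) ~ log(1:8)))[2])
  expect_equal(slope, 1, tolerance = 0.1)
})

test_that("smoother fields have smaller unit-lag increments at equal variance", {
  for (seed in 1:5) {
    roughness <- sapply(c(0.3, 0.7), function(H) {
      f <- fbmField(c(24, 24, 24), H, seed)
      f <- f / sd(f)                       # equal total variance
      mean(abs(diff(f)))
    })
    expect_gt(roughness[1], roughness[2])
  }
})

test_that("phantom output is bit-identical for identical spec and seed", {
  s <- smallPhantomSpec(seed = 5)
  a <- pdaPhantom(s)
  b <- pdaPhantom(smallPhantomSpec(seed = 5))
  expect_identical(voxels(a$stack), voxels(b$stack))
  expect_identical(voxels(a$truth@masks$tumour), voxels(b$truth@masks$tumour))
  c2 <- pdaPhantom(smallPhantomSpec(seed = 6))
  expect_false(identical(voxels(a$stack), voxels(c2$stack)))
})

test_that("truth masks partition the tumour and sizes are self-consistent", {
  ph <- pdaPhantom(smallPhantomSpec(seed = 1))
  tr <- ph$truth
  core <- voxels(tr@masks$core); rim <- voxels(tr@masks$rim)
  expect_false(any(core & rim))
  expect_identical(core | rim, voxels(tr@masks$tumour))
  expect_false(any(voxels(tr@masks$pancreas) & voxels(tr@masks$tumour)))

  for (lab in names(tr@masks))
    expect_identical(tr@trueVolumeMl[[lab]], maskVolumeMl(tr@masks[[lab]]))

  # voxelized ellipsoid volume close to the analytic value
  expect_equal(tr@trueVolumeMl[["core"]], tr@analyticVolumeMl[["core"]],
               tolerance = 0.05)
  expect_equal(tr@trueVolumeMl[["tumour"]], tr@analyticVolumeMl[["tumour"]],
               tolerance = 0.05)
  # Feret of the core close to twice its largest semi-axis
  expect_lte(abs(tr@trueFeretMm[["core"]] - 12), sqrt(3) * 0.7)
})

test_that("spec invariants are enforced", {
  expect_error(phantomSpec(background = list(hurst = 0.2)), "rougher")
  expect_error(phantomSpec(core = list(semiAxesMm = c(-1, 5, 5))), "positive")
  expect_error(phantomSpec(core = list(semiAxesMm = c(40, 40, 40))),
               "outside")
  expect_error(phantomSpec(rim = list(phaseChaos = 1.5)), "phaseChaos")
  expect_error(phantomSpec(portalVein = list(centreMm = c(33, 33))),
               "overlaps")
  expect_error(pdaPhantom(list(a = 1)), "phantomSpec")
})

test_that("zero texture and noise give piecewise-constant phases with FD 4", {
  sp <- smallPhantomSpec(seed = 2, core = list(semiAxesMm = c(6, 5, 4),
                                               amplitude = 0),
                         rim = list(thicknessMm = 2, amplitude = 0),
                         background = list(amplitude = 0), noiseSdHU = 0)
  ph <- pdaPhantom(sp)
  v <- voxels(ph$stack)
  expect_lte(length(unique(as.vector(v[, , , 2]))), 5)
  # region interiors (eroded past the blanket reach) are exactly flat;
  # the enhancement steps at region borders are excluded deliberately
  for (lab in c("core", "pancreas")) {
    m <- voxels(ph$truth@masks[[lab]])
    interior <- m & !dilate3(!m, 4)
    if (!any(interior)) next
    expect_equal(globalFD(ph$stack, interior, scales = 1:4)@fd, 4)
  }
})

test_that("the rim is intensity-matched to background but more chaotic", {
  ph <- pdaPhantom(smallPhantomSpec(seed = 3))
  v <- voxels(ph$stack)
  tr <- ph$truth
  rim <- voxels(tr@masks$rim); bg <- voxels(tr@masks$pancreas)
  coreContrast <- abs(mean(v[, , , 2][voxels(tr@masks$core)]) -
                      mean(v[, , , 2][bg]))
  for (p in 1:3) {
    sl <- v[, , , p]
    # rim-background offset is a small texture residual, far below the
    # core's enhancement contrast
    expect_lt(abs(mean(sl[rim]) - mean(sl[bg])), coreContrast / 3)
  }
  gRim <- globalFD(ph$stack, tr@masks$rim)@fd
  gBg <- globalFD(ph$stack, tr@masks$pancreas)@fd
  expect_gt(gRim, gBg)
})

test_that("FD segmentation recovers tumour volume better than raw contrast", {
  hits <- 0L
  for (seed in 1:3) {
    ph <- pdaPhantom(smallPhantomSpec(seed = seed))
    tr <- ph$truth
    den <- denoiseStack(ph$stack, estimateNoise(ph$stack, tr@masks$muscle))
    nrm <- normalizeEnhancement(den,
             measureReferenceSignals(den, tr@masks$portal_vein))
    fdm <- localFDMap(nrm)
    v <- voxels(fdm)
    thr <- (mean(v[voxels(tr@masks$pancreas)]) +
            mean(v[voxels(tr@masks$rim)])) / 2
    # seed at the most chaotic core voxel (a reader's conspicuous point)
    vc <- v; vc[!voxels(tr@masks$core)] <- -Inf
    seedPt <- arrayInd(which.max(vc), dim(v))
    fdSeg <- segmentFDThreshold(fdm, thr, seedPt)

    # CT-style raw segmentation: portal-phase voxels at core-like contrast
    p3 <- voxels(nrm)[, , , 3]
    coreLvl <- mean(p3[voxels(tr@masks$core)])
    bgLvl <- mean(p3[voxels(tr@masks$pancreas)])
    band <- abs(p3 - coreLvl) <= abs(bgLvl - coreLvl) / 2
    # seed the raw comparator at the most core-like core voxel
    pc <- abs(p3 - coreLvl); pc[!voxels(tr@masks$core)] <- Inf
    seedRaw <- arrayInd(which.min(pc), dim(p3))
    comp <- fractalCT:::cpp_flood26(as.logical(band), as.integer(dim(p3)),
                                    as.integer(seedRaw) - 1L)
    volTruth <- tr@trueVolumeMl[["tumour"]]
    volFD <- maskVolumeMl(fdSeg)
    volRaw <- sum(comp) * prod(voxelSpacing(fdm)) / 1000
    hits <- hits + (abs(volFD - volTruth) < abs(volRaw - volTruth))
  }
  expect_gte(hits, 2L)
})
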