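# Independent reference implementations used as oracles. Deliberately naive
# and written without reference to the package internals.

mirrorIdx <- function(i, n) {
  # 0-based symmetric mirror: -1 -> 0, n -> n-1
  if (n == 1) return(rep(0L, length(i)))
  period <- 2L * n
  i <- ((i %% period) + period) %% period
  ifelse(i < n, i, period - 1L - i)
}

shiftMirror4 <- function(x, axis, by) {
  d <- dim(x)
  idx <- lapply(d, seq_len)
  idx[[axis]] <- mirrorIdx(seq_len(d[axis]) - 1L + by, d[axis]) + 1L
  do.call(`[`, c(list(x), idx))
}

# one blanket step on a 4D array, mirror boundaries, 8 direct neighbours
oracleBlanketStep <- function(x, upper = TRUE) {
  out <- if (upper) x + 1 else x - 1
  for (ax in 1:4) for (s in c(-1L, 1L)) {
    nb <- shiftMirror4(x, ax, s)
    out <- if (upper) pmax(out, nb) else pmin(out, nb)
  }
  out
}

oracleBlanketVolumes <- function(tex, maxeps) {
  u <- tex; b <- tex
  V <- numeric(maxeps)
  for (e in seq_len(maxeps)) {
    u <- oracleBlanketStep(u, TRUE)
    b <- oracleBlanketStep(b, FALSE)
    V[e] <- sum(u - b)
  }
  V
}

# per-voxel FD by materializing every window independently
oracleLocalFD <- function(tex, wr, scales, centerPhases = TRUE) {
  d <- dim(tex)
  np <- d[4]
  out <- array(NA_real_, d[1:3])
  lx <- log(scales)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    ix <- mirrorIdx((x - 1) + (-wr:wr), d[1]) + 1L
    iy <- mirrorIdx((y - 1) + (-wr:wr), d[2]) + 1L
    iz <- mirrorIdx((z - 1) + (-wr:wr), d[3]) + 1L
    win <- tex[ix, iy, iz, , drop = FALSE]
    if (centerPhases)
      for (p in seq_len(np)) win[, , , p] <- win[, , , p] - mean(win[, , , p])
    V <- oracleBlanketVolumes(win, max(scales))
    A <- (diff(c(0, V)) / 2)[scales]
    fd <- if (any(A <= 0)) 4 else {
      4 - unname(coef(lm(log(A) ~ lx))[2])
    }
    out[x, y, z] <- min(max(fd, 4), 5)
  }
  out
}

# exhaustive pairwise Feret diameter in mm
oracleFeret <- function(maskArr, spacing) {
  idx <- which(maskArr, arr.ind = TRUE)
  mm <- sweep(idx - 1, 2, spacing, `*`)
  best <- 0
  for (i in seq_len(nrow(mm) - 1)) {
    d2 <- (mm[(i + 1):nrow(mm), 1] - mm[i, 1])^2 +
          (mm[(i + 1):nrow(mm), 2] - mm[i, 2])^2 +
          (mm[(i + 1):nrow(mm), 3] - mm[i, 3])^2
    best <- max(best, max(d2))
  }
  sqrt(best)
}

# exact two-sided Mann-Whitney p-value by exhaustive enumeration of all
# assignments of the pooled ranks to group 1
oracleRankSumP <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- combn(length(pooled), n1)
  us <- apply(combs, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  mu <- length(x) * length(y) / 2
  mean(abs(us - mu) >= abs(uObs - mu) - 1e-9)
}

# exact two-sided signed-rank p-value by enumerating all sign assignments
oracleSignedRankP <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  vObs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  mu <- n * (n + 1) / 4
  mean(abs(vs - mu) >= abs(vObs - mu) - 1e-9)
}

# Chebyshev (L-infinity) dilation: axis-sequential within each iteration
dilateCheb <- function(m, k) {
  d <- dim(m)
  for (i in seq_len(k)) {
    for (ax in 1:3) {
      idxLo <- lapply(d, seq_len); idxHi <- idxLo
      idxLo[[ax]] <- pmax(seq_len(d[ax]) - 1L, 1L)
      idxHi[[ax]] <- pmin(seq_len(d[ax]) + 1L, d[ax])
      m <- m | do.call(`[`, c(list(m), idxLo)) |
        do.call(`[`, c(list(m), idxHi))
    }
  }
  m
}

dilate3 <- function(m, k) {
  d <- dim(m)
  for (i in seq_len(k)) {
    out <- m
    out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
    out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
    out[, , -1] <- out[, , -1] | m[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
    m <- out
  }
  m
}

# small phantom spec that fits a 48^3-ish grid, for fast pipeline tests
smallPhantomSpec <- function(seed, gridShape = c(48L, 48L, 36L),
                             core = list(), rim = list(),
                             background = list(), noiseSdHU = 5) {
  ext <- (gridShape - 1) * 0.7
  phantomSpec(gridShape = gridShape, seed = seed,
              core = utils::modifyList(list(semiAxesMm = c(6, 5, 4)), core),
              rim = utils::modifyList(list(thicknessMm = 2), rim),
              background = background,
              portalVein = list(centreMm = c(0.85, 0.18) * ext[1:2],
                                radiusMm = 2.5),
              muscle = list(xlimMm = c(1.5, 6), ylimMm = c(1.5, 6),
                            zlimMm = c(1.5, min(20, ext[3] - 1.5))),
              noiseSdHU = noiseSdHU)
}
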