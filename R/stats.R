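#' @include AllClasses.R
NULL

#' Bland-Altman agreement of a test method against a reference
#'
#' Differences follow the reference-minus-test convention, so a positive
#' mean difference means the test method underestimates. Limits of
#' agreement are the classical `mean +- 1.96 * SD` of the differences.
#' Two regressions accompany them: difference on pairwise mean
#' (proportional-bias check) and test on reference (calibration line with
#' R-squared); because published agreement tables differ in orientation,
#' the slope and intercept of reference-on-test are also reported.
#'
#' @param reference Numeric vector of reference measurements.
#' @param test Numeric vector of candidate-method measurements, same length
#'   (>= 3).
#' @return An [AgreementStats-class].
#' @examples
#' ba <- blandAltman(1:10, 0.8 * (1:10))
#' ba  # mean difference 1.1, slope 0.8
#' @export
blandAltman <- function(reference, test) {
  if (length(reference) != length(test)) stop("length mismatch")
  n <- length(reference)
  if (n < 3L) stop("need at least 3 pairs")
  diffs <- reference - test
  means <- (reference + test) / 2
  md <- mean(diffs)
  s <- stats::sd(diffs)
  propFit <- stats::lm(diffs ~ means)
  corrFit <- stats::lm(test ~ reference)
  revFit <- stats::lm(reference ~ test)
  ciOf <- function(fit) {
    ci <- suppressWarnings(stats::confint(fit))
    m <- rbind(slope = ci[2, ], intercept = ci[1, ])
    m[!is.finite(m)] <- NA_real_
    m
  }
  r2 <- suppressWarnings(summary(corrFit)$r.squared)
  if (!is.finite(r2)) r2 <- 1
  methods::new("AgreementStats",
    meanDiff = md, lowerLimit = md - 1.96 * s, upperLimit = md + 1.96 * s,
    propSlope = unname(stats::coef(propFit)[2]),
    propIntercept = unname(stats::coef(propFit)[1]),
    propCI = ciOf(propFit),
    corrSlope = unname(stats::coef(corrFit)[2]),
    corrIntercept = unname(stats::coef(corrFit)[1]),
    corrCI = ciOf(corrFit),
    r2 = min(max(r2, 0), 1),
    refOnTest = c(slope = unname(stats::coef(revFit)[2]),
                  intercept = unname(stats::coef(revFit)[1])),
    n = as.integer(n))
}

#' Kruskal-Wallis omnibus plus pairwise rank tests
#'
#' Group differences in FD or size measurements: an omnibus Kruskal-Wallis
#' test followed by all pairwise comparisons, Bonferroni-corrected. The
#' pairwise family is the Mann-Whitney U (rank-sum) test for independent
#' groups or the Wilcoxon signed-rank test when `paired = TRUE` (the
#' paired member of that family). Exact p-values are used when every group
#' has at most 10 observations and no ties intervene; otherwise the normal
#' approximation with tie correction applies.
#'
#' @param groups Named list of numeric vectors (>= 2 groups).
#' @param paired Use the signed-rank test on paired groups (equal lengths
#'   required).
#' @return data.frame with one row per test: `method`, `comparison`,
#'   `statistic`, `p_raw`, `p_adjusted`, `n_comparisons`.
#' @export
rankTests <- function(groups, paired = FALSE) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(vapply(groups, length, integer(1)) == 0L)) stop("empty group")
  if (paired && length(unique(vapply(groups, length, integer(1)))) != 1L)
    stop("paired tests require equal group lengths")
  kw <- stats::kruskal.test(groups)
  pairsIdx <- utils::combn(length(groups), 2)
  k <- ncol(pairsIdx)
  useExact <- max(vapply(groups, length, integer(1))) <= 10L
  rows <- lapply(seq_len(k), function(j) {
    i1 <- pairsIdx[1, j]; i2 <- pairsIdx[2, j]
    wt <- suppressWarnings(stats::wilcox.test(
      groups[[i1]], groups[[i2]], paired = paired, exact = useExact))
    data.frame(
      method = if (paired) "wilcoxon_signed_rank" else "mann_whitney_u",
      comparison = paste(names(groups)[i1], "vs", names(groups)[i2]),
      statistic = unname(wt$statistic),
      p_raw = wt$p.value,
      p_adjusted = min(1, wt$p.value * k),
      n_comparisons = k, stringsAsFactors = FALSE)
  })
  rbind(
    data.frame(method = "kruskal_wallis", comparison = "omnibus",
               statistic = unname(kw$statistic), p_raw = kw$p.value,
               p_adjusted = kw$p.value, n_comparisons = 1L,
               stringsAsFactors = FALSE),
    do.call(rbind, rows))
}

#' Inter-reader agreement of size measurements
#'
#' Per-case relative discrepancy `|r1 - r2| / mean(r1, r2) * 100` (the
#' pairwise-mean denominator keeps the measure symmetric in the readers),
#' summarized by median and interquartile range, plus Spearman's rho.
#'
#' @param reader1,reader2 Positive numeric vectors of equal length (>= 3).
#' @return List with `medianDiscrepancy`, `iqrDiscrepancy` (both %),
#'   `rho`, and the per-case `discrepancies`.
#' @export
interReaderAgreement <- function(reader1, reader2) {
  if (length(reader1) != length(reader2)) stop("length mismatch")
  if (length(reader1) < 3L) stop("need at least 3 cases")
  if (any(reader1 <= 0) || any(reader2 <= 0))
    stop("sizes must be positive")
  disc <- abs(reader1 - reader2) / ((reader1 + reader2) / 2) * 100
  list(medianDiscrepancy = stats::median(disc),
       iqrDiscrepancy = stats::IQR(disc),
       rho = stats::cor(reader1, reader2, method = "spearman"),
       discrepancies = disc)
}

#' F-test comparing variances of two sets of differences
#'
#' The statistic is the larger sample variance over the smaller, with a
#' two-sided p-value from the F distribution at the matching degrees of
#' freedom.
#'
#' @param diffsA,diffsB Numeric vectors (each n >= 2).
#' @return One-row data.frame: `statistic` (F), `df1`, `df2`, `p_raw`,
#'   `p_adjusted`, `method`, `n_comparisons`.
#' @export
varianceFTest <- function(diffsA, diffsB) {
  if (length(diffsA) < 2L || length(diffsB) < 2L)
    stop("each sample needs n >= 2")
  va <- stats::var(diffsA); vb <- stats::var(diffsB)
  if (va == 0 && vb == 0) stop("zero variance in both samples")
  if (va >= vb) {
    f <- if (vb == 0) Inf else va / vb
    df1 <- length(diffsA) - 1L; df2 <- length(diffsB) - 1L
  } else {
    f <- vb / va
    df1 <- length(diffsB) - 1L; df2 <- length(diffsA) - 1L
  }
  p <- min(1, 2 * stats::pf(f, df1, df2, lower.tail = FALSE))
  data.frame(statistic = f, df1 = df1, df2 = df2, p_raw = p,
             p_adjusted = p, method = "f_test_of_variances",
             n_comparisons = 1L, stringsAsFactors = FALSE)
}
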