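## Per-position G-test of independence between sample and control tracks.

#' Critical value of the G statistic
#'
#' The conventional threshold for the 1% level is the 0.99 quantile of the
#' chi-squared distribution with 1 df truncated (not rounded) to three
#' decimals, 6.634.
#'
#' @param alpha significance level.
#' @param digits decimals to truncate to.
#' @return the critical G value.
#' @export
gCriticalValue <- function(alpha = 0.01, digits = 3L) {
  q <- qchisq(1 - alpha, df = 1)
  floor(q * 10^digits) / 10^digits
}

## Vectorized G statistic for 2x2 tables [[a, A-a], [b, B-b]] with both
## margins observed ("model II" independence design).  Zero cells
## contribute 0; optionally divided by Williams' correction factor.
gStatistic <- function(a, A, b, B, williams = FALSE) {
  o11 <- a; o12 <- A - a; o21 <- b; o22 <- B - b
  N <- A + B
  r1 <- o11 + o21
  r2 <- o12 + o22
  term <- function(o, e) ifelse(o > 0, o * log(o / e), 0)
  G <- 2 * (term(o11, r1 * A / N) + term(o12, r2 * A / N) +
            term(o21, r1 * B / N) + term(o22, r2 * B / N))
  G <- pmax(G, 0)
  if (williams) {
    q <- 1 + ((N / r1 + N / r2 - 1) * (N / A + N / B - 1)) / (6 * N)
    q[!is.finite(q)] <- 1
    G <- G / q
  }
  G
}

#' G-test of independence on one 2x2 table
#'
#' Tests whether the proportion of matching reads differs between sample
#' (`sampleCount` of `sampleTotal`) and control (`controlCount` of
#' `controlTotal`).  With observed cells `O = [[a, A-a], [b, B-b]]` and
#' expectations `E_ij = row_i * col_j / N`, `G = 2 * sum(O * ln(O/E))`
#' (zero cells contribute nothing), asymptotically chi-squared with 1 df.
#' Direction compares `a/A` with `b/B`.
#'
#' @param sampleCount,sampleTotal matching reads and total reads in the
#'   sample.
#' @param controlCount,controlTotal matching reads and total reads in the
#'   control.
#' @param config an [AnalysisConfig-class]; `gCritical` and `williams`
#'   are used.
#' @return a [GTestResult-class].
#' @export
gTest2x2 <- function(sampleCount, sampleTotal, controlCount, controlTotal,
                     config = AnalysisConfig()) {
  a <- as.numeric(sampleCount); A <- as.numeric(sampleTotal)
  b <- as.numeric(controlCount); B <- as.numeric(controlTotal)
  if (A <= 0 || B <= 0) stop("totals must be > 0")
  if (a < 0 || b < 0 || a > A || b > B)
    stop("counts must satisfy 0 <= count <= total")
  G <- gStatistic(a, A, b, B, williams = config@williams)
  cross <- a * B - b * A
  dir <- if (G == 0 || cross == 0) "none"
         else if (cross > 0) "sample_enriched" else "control_enriched"
  new("GTestResult", g = G, direction = dir,
      significant = G > config@gCritical && dir != "none")
}

#' Per-position G-test of a sample track against a control track
#'
#' Applies [gTest2x2()] at every vector position, using each track's total
#' read count as the table margins.  With `multipleTesting = "bonferroni"`
#' the critical value is recomputed as the chi-squared(1) quantile at
#' `alpha / m`, where `m` is the number of positions with a nonzero count
#' in either track (positions at zero in both give G = 0 and are never
#' significant, so they are not live tests).
#'
#' @param sample,control [PositionCountTrack-class]s of equal length.
#' @param config an [AnalysisConfig-class].
#' @return a [SignificanceTrack-class].
#' @export
testTrack <- function(sample, control, config = AnalysisConfig()) {
  if (length(sample@counts) != length(control@counts) || sample@k != control@k)
    stop("sample and control tracks have mismatched dimensions")
  if (sample@totalReads <= 0L || control@totalReads <= 0L)
    stop("both tracks must have totalReads > 0")
  a <- as.numeric(sample@counts)
  b <- as.numeric(control@counts)
  A <- as.numeric(sample@totalReads)
  B <- as.numeric(control@totalReads)
  gcrit <- config@gCritical
  if (config@multipleTesting == "bonferroni") {
    m <- sum(a > 0 | b > 0)
    if (m > 0L) gcrit <- qchisq(1 - config@alpha / m, df = 1)
  }
  G <- gStatistic(a, A, b, B, williams = config@williams)
  cross <- a * B - b * A
  dir <- ifelse(G == 0 | cross == 0, "none",
                ifelse(cross > 0, "sample_enriched", "control_enriched"))
  sig <- G > gcrit & dir != "none"
  stats <- data.frame(
    position = seq_along(a),
    sampleCount = sample@counts,
    controlCount = control@counts,
    G = G, direction = dir, significant = sig,
    stringsAsFactors = FALSE)
  new("SignificanceTrack", stats = stats,
      sampleTotal = sample@totalReads, controlTotal = control@totalReads,
      gCritical = gcrit, k = sample@k, vectorId = sample@vectorId)
}
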