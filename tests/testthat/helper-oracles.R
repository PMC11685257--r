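# Independent oracles and small builders used across the suite.

# G as twice the log-likelihood ratio of two free binomials against a
# pooled binomial -- an independent route to the 2x2 independence G.
gOracle <- function(a, A, b, B) {
  p <- (a + b) / (A + B)
  ll1 <- dbinom(a, A, a / A, log = TRUE) + dbinom(b, B, b / B, log = TRUE)
  ll0 <- dbinom(a, A, p, log = TRUE) + dbinom(b, B, p, log = TRUE)
  2 * (ll1 - ll0)
}

# Brute-force per-position read counting: a read supports vector position
# p iff the vector window starting at p occurs in the read or in its
# reverse complement.
scanOracle <- function(reads, vec, k) {
  npos <- nchar(vec) - k + 1L
  rcs <- revcompChar(reads)
  vapply(seq_len(npos), function(p) {
    w <- substr(vec, p, p + k - 1L)
    sum(mapply(function(r, rc)
      grepl(w, r, fixed = TRUE) || grepl(w, rc, fixed = TRUE),
      reads, rcs))
  }, integer(1))
}

# Full-matrix Gotoh score (no rolling rows, no traceback): an independent
# reference for the aligner on short sequences.
alignScoreOracle <- function(ref, qry, match = 2, mismatch = -3,
                             open = -6, ext = -1) {
  r <- strsplit(ref, "")[[1]]
  q <- strsplit(qry, "")[[1]]
  n <- length(r); m <- length(q)
  NEG <- -1e18
  M <- X <- Y <- matrix(NEG, n + 1L, m + 1L)
  M[1, 1] <- 0
  if (n) X[2:(n + 1), 1] <- open + (0:(n - 1)) * ext
  if (m) Y[1, 2:(m + 1)] <- open + (0:(m - 1)) * ext
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (r[i - 1] == q[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] + open, X[i - 1, j] + ext, Y[i - 1, j] + open)
      Y[i, j] <- max(M[i, j - 1] + open, X[i, j - 1] + open, Y[i, j - 1] + ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Count track for a simulated read pair set.
trackOf <- function(pairs, idx) {
  combineTracks(list(scanReads(pairs$mate1, idx), scanReads(pairs$mate2, idx)))
}

# Simulate an experiment and run it through scan -> test -> verdict.
syntheticVerdict <- function(config, edit = EditSpec("deletion", 2L),
                             foreignLen = 0L) {
  ex <- simulateExperiment(config, edit = edit, foreignLen = foreignLen)
  idx <- buildKmerIndex(vectorSequence(ex$vector), AnalysisConfig(), "vector")
  st <- trackOf(ex$sampleReads, idx)
  ct <- trackOf(ex$controlReads, idx)
  sig <- testTrack(st, ct)
  pk <- callPeaks(sig)
  cl <- classifyPeaks(pk, st, ct, vector = ex$vector)
  list(experiment = ex, sample = st, control = ct, significance = sig,
       verdict = renderVerdict(cl))
}

# A SignificanceTrack with prescribed significant positions, built from
# crafted counts (40 supporting reads force significance at these totals).
craftedSignificance <- function(npos, samplePos = integer(0),
                                controlPos = integer(0), total = 100000L) {
  a <- integer(npos); a[samplePos] <- 40L
  b <- integer(npos); b[controlPos] <- 40L
  both <- intersect(samplePos, controlPos)
  a[both] <- 40L; b[both] <- 40L
  testTrack(PositionCountTrack(a, total), PositionCountTrack(b, total))
}

randomReadFrom <- function(genome, len) {
  s <- as.character(genome)
  p <- sample.int(nchar(s) - len + 1L, 1L)
  substr(s, p, p + len - 1L)
}
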