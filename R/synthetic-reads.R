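## Paired-end read simulation.

#' Simulate paired-end reads from a genome
#'
#' Fragments are placed uniformly over the genome with lengths drawn from
#' normal(`insertMean`, `insertSd`) truncated below at the read length (and
#' above at the genome length).  Mate 1 is the fragment 5' end; mate 2 is
#' the reverse complement of the fragment 3' end.  Substitution errors are
#' applied per base at `errorRate`.  The number of pairs is
#' `round(coverage * genomeLength / (2 * readLength))`.
#'
#' @param genome a [StrainGenome-class] (single contig).
#' @param config a [SimConfig-class]; `coverage`, `readLength`,
#'   `insertMean`, `insertSd`, `errorRate` and `seed` are used.
#' @param seed optional seed overriding `config@seed`.
#' @return list with elements `mate1` and `mate2`, each a named
#'   [Biostrings::DNAStringSet] of equal length.
#' @export
simulateReads <- function(genome, config, seed = config@seed) {
  validObject(config)
  if (config@coverage <= 0) stop("'coverage' must be > 0")
  s <- as.character(genome@sequences[[1L]])
  L <- nchar(s)
  rl <- config@readLength
  if (L < config@insertMean)
    stop("genome shorter than the mean insert size")
  set.seed(seed)
  nPairs <- as.integer(round(config@coverage * L / (2 * rl)))
  fragLen <- as.integer(round(rnorm(nPairs, config@insertMean, config@insertSd)))
  fragLen <- pmin(pmax(fragLen, rl), L)
  start <- 1L + as.integer(floor(runif(nPairs) * (L - fragLen + 1L)))
  m1 <- substring(s, start, start + rl - 1L)
  m2 <- revcompChar(substring(s, start + fragLen - rl, start + fragLen - 1L))
  if (config@errorRate > 0) {
    reads <- c(m1, m2)
    tb <- length(reads) * rl
    err <- which(runif(tb) < config@errorRate)
    if (length(err)) {
      ri <- ((err - 1L) %/% rl) + 1L
      off <- ((err - 1L) %% rl) + 1L
      bases <- c("A", "C", "G", "T")
      for (j in seq_along(err)) {
        old <- substr(reads[ri[j]], off[j], off[j])
        new <- sample(setdiff(bases, old), 1L)
        substr(reads[ri[j]], off[j], off[j]) <- new
      }
    }
    m1 <- reads[seq_len(nPairs)]
    m2 <- reads[nPairs + seq_len(nPairs)]
  }
  ids <- sprintf("%s_%06d", genome@label, seq_len(nPairs))
  mate1 <- Biostrings::DNAStringSet(m1)
  names(mate1) <- paste0(ids, "/1")
  mate2 <- Biostrings::DNAStringSet(m2)
  names(mate2) <- paste0(ids, "/2")
  list(mate1 = mate1, mate2 = mate2)
}

#' Write simulated read pairs as FASTQ
#'
#' Qualities are constant (Phred 40, 'I'); the downstream k-mer analysis
#' ignores base qualities.
#'
#' @param pairs list with `mate1`/`mate2` as returned by [simulateReads()].
#' @param prefix output path prefix; files `<prefix>_R1.fastq[.gz]` and
#'   `<prefix>_R2.fastq[.gz]` are written.
#' @param compress write gzipped FASTQ (default TRUE).
#' @return invisibly, the two file paths.
#' @export
writeReadsFastq <- function(pairs, prefix, compress = TRUE) {
  ext <- if (compress) ".fastq.gz" else ".fastq"
  paths <- paste0(prefix, c("_R1", "_R2"), ext)
  for (i in 1:2) {
    x <- pairs[[i]]
    q <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
    Biostrings::writeXStringSet(x, paths[i], format = "fastq",
                                compress = compress, qualities = q)
  }
  invisible(paths)
}
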