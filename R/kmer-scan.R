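## Canonical k-mer index of the vector and read scanning: the pipeline's
## data reduction from a read set to a per-vector-position count track.

#' Build a canonical k-mer index of a vector sequence
#'
#' Every length-k window of the vector is stored under its canonical form
#' (lexicographic minimum of the window and its reverse complement), mapped
#' to its 1-based start position(s).  Windows containing non-ACGT bases are
#' skipped.
#'
#' @param vectorSequence the vector as a character string,
#'   [Biostrings::DNAString] or single-element [Biostrings::DNAStringSet].
#' @param config an [AnalysisConfig-class] (only `k` is used).
#' @param vectorId identifier stored with the index.
#' @return a [KmerIndex-class].
#' @export
buildKmerIndex <- function(vectorSequence, config = AnalysisConfig(),
                           vectorId = "vector") {
  if (is(vectorSequence, "DNAStringSet")) {
    if (length(vectorSequence) != 1L)
      stop("expected a single vector sequence")
    if (!is.null(names(vectorSequence)) && missing(vectorId))
      vectorId <- names(vectorSequence)[1L]
    vectorSequence <- vectorSequence[[1L]]
  }
  s <- toupper(as.character(vectorSequence))
  k <- config@k
  if (nchar(s) < k)
    stop("vector (", nchar(s), " bp) is shorter than k = ", k)
  tab <- kmerWindowTable(s, k)
  tab$kmer <- canonicalKmers(tab$kmer)
  tbl <- data.table::data.table(kmer = tab$kmer, pos = tab$start)
  data.table::setkeyv(tbl, "kmer")
  new("KmerIndex", k = k, vectorLength = nchar(s),
      vectorId = as.character(vectorId), table = as.data.frame(tbl))
}

#' Scan reads against a k-mer index
#'
#' Every length-k window of every read is canonicalized and looked up in
#' the index; each vector position matched by at least one window of a read
#' is incremented by exactly one for that read (per-read counting, so a
#' position's count is the number of reads containing that 20-mer and is
#' bounded by the sequencing depth).  Both mates of a pair count as
#' separate reads.  An empty read set yields an all-zero track with
#' `totalReads = 0`.
#'
#' @param reads a [Biostrings::DNAStringSet] or character vector of reads
#'   (FASTA and FASTQ input are read with [readSequences()]).
#' @param index a [KmerIndex-class].
#' @return a [PositionCountTrack-class].
#' @export
scanReads <- function(reads, index) {
  if (is(reads, "XStringSet")) reads <- as.character(reads)
  reads <- toupper(reads)
  k <- index@k
  npos <- index@vectorLength - k + 1L
  if (!length(reads))
    return(PositionCountTrack(integer(npos), 0L, k, index@vectorId))
  dt <- kmerWindowTable(reads, k)
  cnts <- integer(npos)
  if (nrow(dt)) {
    dt$kmer <- canonicalKmers(dt$kmer)
    idx <- data.table::as.data.table(index@table)
    hits <- idx[dt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(hits)) {
      hits <- unique(hits[, c("id", "pos")])
      cnts <- tabulate(hits$pos, nbins = npos)
    }
  }
  PositionCountTrack(cnts, length(reads), k, index@vectorId)
}

#' Combine count tracks
#'
#' Element-wise sum of per-position counts; total read counts add.  Used to
#' merge mates, lanes or files scanned separately.
#'
#' @param tracks list of [PositionCountTrack-class] objects over the same
#'   vector and k.
#' @return the combined [PositionCountTrack-class].
#' @export
combineTracks <- function(tracks) {
  if (!length(tracks)) stop("no tracks to combine")
  t1 <- tracks[[1L]]
  for (t in tracks[-1L]) {
    if (length(t@counts) != length(t1@counts) || t@k != t1@k)
      stop("tracks have mismatched dimensions")
  }
  cnts <- Reduce(`+`, lapply(tracks, function(t) t@counts))
  tot <- sum(vapply(tracks, function(t) t@totalReads, integer(1)))
  PositionCountTrack(cnts, tot, t1@k, t1@vectorId)
}
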