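## Low-level sequence helpers shared by the simulator and the scanner.

#' Reverse complement of character-mode DNA sequences
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements.
#' @export
revcompChar <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical form of k-mers
#'
#' The canonical form of a k-mer is the lexicographic minimum of the k-mer
#' and its reverse complement; matching canonical forms implements
#' both-strand matching symmetrically for reads and vector.
#'
#' @param x character vector of k-mers (all the same length).
#' @return character vector of canonical k-mers.
#' @export
canonicalKmers <- function(x) {
  if (!length(x)) return(character(0))
  pmin(x, revcompChar(x))
}

## All length-k windows of each sequence, as a data.table(id, start, kmer).
## Windows containing non-ACGT characters are dropped.
kmerWindowTable <- function(seqs, k) {
  w <- nchar(seqs)
  n <- pmax(w - k + 1L, 0L)
  id <- rep.int(seq_along(seqs), n)
  start <- sequence(n)
  kmer <- substring(seqs[id], start, start + k - 1L)
  keep <- !grepl("[^ACGT]", kmer)
  data.table::data.table(id = id[keep], start = start[keep],
                         kmer = kmer[keep])
}

#' Random DNA sequence with a given GC content
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc/2 and P(A) = P(T) =
#' (1 - gc)/2.  Uses the current RNG state; seed upstream for
#' reproducibility.
#'
#' @param n sequence length in bp.
#' @param gc GC fraction in `[0, 1]`.
#' @return a single character string of length `n`.
#' @export
randomDNA <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## Substitute characters at flat positions `pos` of string `s` with `base`.
substituteBases <- function(s, pos, base) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  v[pos] <- base
  paste(v, collapse = "")
}

## Reference coordinate of the base immediately 5' of the Cas9 blunt cut
## (cut between protospacer positions 17 and 18, 3 bp from the PAM).
cutSiteAfter <- function(site) {
  if (site@strand == "+") site@start + 16L else site@end - 17L
}

## Protospacer+PAM window in reference coordinates.
targetWindow <- function(site) {
  if (site@strand == "+")
    c(site@start, site@end + 3L)
  else
    c(site@start - 3L, site@end)
}
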