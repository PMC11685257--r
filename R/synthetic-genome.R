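## Synthetic-experiment generators: genomes, strains, edits, vector.
## Every generator seeds the RNG explicitly, so results are reproducible
## given the configuration.

#' Generate a progenitor genome
#'
#' Draws a single-contig random genome with i.i.d. bases at the configured
#' GC fraction.
#'
#' @param config a [SimConfig-class].
#' @param label strain label.
#' @param contig contig name.
#' @return a [StrainGenome-class] with an empty SNV table.
#' @export
generateProgenitorGenome <- function(config, label = "progenitor",
                                     contig = "chr1") {
  validObject(config)
  set.seed(config@seed)
  seqs <- Biostrings::DNAStringSet(randomDNA(config@genomeLength,
                                             config@gcContent))
  names(seqs) <- contig
  StrainGenome(label, seqs)
}

#' Derive a strain by scattering SNVs over a progenitor
#'
#' Each position outside the protected windows mutates independently with
#' probability `snvRate` to one of the three other bases (uniformly).
#' Protected windows (by default the protospacer+PAM of each target site)
#' stay intact so the target remains editable in both strains.
#'
#' @param progenitor a [StrainGenome-class].
#' @param snvRate per-bp substitution probability in `[0, 1)`.
#' @param protectedWindows an [IRanges::IRanges] of 1-based windows (on the
#'   single contig) in which no SNV may fall, or `NULL`.
#' @param seed integer seed.
#' @param label label of the derived strain.
#' @return a [StrainGenome-class] whose `snvs` slot records every change
#'   relative to the progenitor.
#' @export
deriveStrain <- function(progenitor, snvRate, protectedWindows = NULL,
                         seed = 1L, label = "derived") {
  if (snvRate < 0 || snvRate >= 1)
    stop("'snvRate' must lie in [0, 1)")
  set.seed(seed)
  contig <- names(progenitor@sequences)[1L]
  s <- as.character(progenitor@sequences[[1L]])
  L <- nchar(s)
  if (!is.null(protectedWindows)) {
    if (length(protectedWindows) &&
        (min(IRanges::start(protectedWindows)) < 1L ||
         max(IRanges::end(protectedWindows)) > L))
      stop("protected windows fall outside the genome")
  }
  hit <- which(runif(L) < snvRate)
  if (!is.null(protectedWindows) && length(hit)) {
    prot <- IRanges::overlapsAny(IRanges::IRanges(hit, width = 1L),
                                 protectedWindows)
    hit <- hit[!prot]
  }
  if (length(hit)) {
    refs <- substring(s, hit, hit)
    bases <- c("A", "C", "G", "T")
    alts <- vapply(refs, function(b) sample(setdiff(bases, b), 1L), "",
                   USE.NAMES = FALSE)
    s <- substituteBases(s, hit, alts)
    snvs <- data.frame(contig = contig, pos = hit, ref = refs, alt = alts,
                       stringsAsFactors = FALSE)
  } else {
    snvs <- data.frame(contig = character(0), pos = integer(0),
                       ref = character(0), alt = character(0))
  }
  seqs <- Biostrings::DNAStringSet(s)
  names(seqs) <- contig
  StrainGenome(label, seqs, snvs)
}

#' Apply a programmed edit at a target site
#'
#' Deletions remove `size` bases centred (per `offset`) on the cut site;
#' insertions add `insertedSeq` at the cut site; substitutions replace
#' `size` bases 3' of the cut with different bases (a fixed transversion
#' map, so the outcome is deterministic).  `large_deletion` behaves as
#' `deletion` and is intended to span primer-binding or k-mer-anchor
#' coordinates, emulating loss of PCR amplification.
#'
#' @param genome a [StrainGenome-class] (single contig).
#' @param site a [TargetSite-class].
#' @param spec an [EditSpec-class].
#' @param label label of the edited genome.
#' @return the edited [StrainGenome-class]; genome length changes by
#'   +/- `size` for indels.
#' @export
applyEdit <- function(genome, site, spec, label = paste0(genome@label, "_edited")) {
  validObject(spec)
  s <- as.character(genome@sequences[[1L]])
  L <- nchar(s)
  if (site@start < 1L || site@end > L)
    stop("target site outside the contig")
  cut <- cutSiteAfter(site)
  if (spec@kind %in% c("deletion", "large_deletion")) {
    delStart <- cut + spec@offset - as.integer(ceiling(spec@size / 2)) + 1L
    delEnd <- delStart + spec@size - 1L
    if (delStart < 1L || delEnd > L)
      stop("edit extends past the contig end")
    s <- paste0(substr(s, 1L, delStart - 1L), substr(s, delEnd + 1L, L))
  } else if (spec@kind == "insertion") {
    at <- cut + spec@offset
    if (at < 0L || at > L)
      stop("edit extends past the contig end")
    s <- paste0(substr(s, 1L, at), spec@insertedSeq, substr(s, at + 1L, L))
  } else { # substitution
    subStart <- cut + spec@offset + 1L
    subEnd <- subStart + spec@size - 1L
    if (subStart < 1L || subEnd > L)
      stop("edit extends past the contig end")
    orig <- substr(s, subStart, subEnd)
    repl <- chartr("ACGT", "CATG", orig)
    s <- paste0(substr(s, 1L, subStart - 1L), repl, substr(s, subEnd + 1L, L))
  }
  seqs <- Biostrings::DNAStringSet(s)
  names(seqs) <- names(genome@sequences)[1L]
  StrainGenome(label, seqs, genome@snvs)
}

#' Default vector feature lengths
#'
#' A nine-feature layout modelled on a fungal CRISPR/Cas9 transformation
#' plasmid: an E. coli origin, a bacterial selection marker, a terminator,
#' an NLS, a codon-optimised Cas9, its promoter, a U6 promoter driving the
#' gRNA, the 20-bp spacer itself, and a fungal selection marker.
#'
#' @return named integer vector of feature lengths (bp).
#' @export
defaultVectorFeatures <- function() {
  c(pUC_ori = 600L, kmR = 1000L, Abhsp26_ter = 300L, NLS = 21L,
    fcocas9 = 4100L, Ccef3_pro = 2000L, CcU6_pro = 96L,
    gRNA_spacer = 20L, hph = 1030L)
}

#' Extract the protospacer sequence of a target site
#'
#' @param genome a [StrainGenome-class].
#' @param site a [TargetSite-class].
#' @return the 20-base protospacer as read on the site's strand.
#' @export
protospacerSequence <- function(genome, site) {
  s <- as.character(genome@sequences[[1L]])
  p <- substr(s, site@start, site@end)
  if (site@strand == "-") p <- revcompChar(p)
  p
}

#' Build an annotated transformation vector
#'
#' Random feature sequences are drawn at GC 0.5, the spacer feature is
#' copied verbatim from the host protospacer, and the vector is re-scanned
#' against the host genome: any shared canonical k-mer other than the
#' spacer window triggers regeneration of the colliding feature, so that by
#' construction the spacer is the only >= k-bp exact match between vector
#' and host.
#'
#' @param featureLengths named integer vector of feature lengths, in vector
#'   order; the spacer feature must have length 20.
#' @param host the [StrainGenome-class] carrying the protospacer.
#' @param site the [TargetSite-class] whose protospacer the vector carries.
#' @param spacerFeature name of the spacer feature.
#' @param k word size used for the uniqueness scan (default 20).
#' @param seed integer seed.
#' @param maxIter resampling attempts before giving up.
#' @return a [VectorModel-class].
#' @export
buildVector <- function(featureLengths = defaultVectorFeatures(), host, site,
                        spacerFeature = "gRNA_spacer", k = 20L, seed = 1L,
                        maxIter = 50L) {
  if (!spacerFeature %in% names(featureLengths))
    stop("'spacerFeature' not among the feature names")
  if (sum(names(featureLengths) == spacerFeature) != 1L)
    stop("exactly one feature must be the spacer feature")
  if (featureLengths[[spacerFeature]] != 20L)
    stop("the spacer feature must be exactly 20 bp")
  set.seed(seed)
  spacerSeq <- protospacerSequence(host, site)
  feats <- vapply(seq_along(featureLengths), function(i) {
    if (names(featureLengths)[i] == spacerFeature) spacerSeq
    else randomDNA(featureLengths[[i]])
  }, "")
  names(feats) <- names(featureLengths)

  hostKmers <- unique(canonicalKmers(
    kmerWindowTable(as.character(host@sequences[[1L]]), k)$kmer))

  for (iter in seq_len(maxIter)) {
    full <- paste(feats, collapse = "")
    vw <- kmerWindowTable(full, k)
    vw$kmer <- canonicalKmers(vw$kmer)
    fr <- IRanges::IRanges(
      start = cumsum(c(1L, unname(featureLengths[-length(featureLengths)]))),
      width = unname(featureLengths), names = names(featureLengths))
    spacerStart <- IRanges::start(fr[spacerFeature])
    allowed <- spacerStart  # the single fully-internal spacer window
    shared <- vw$start[vw$kmer %in% hostKmers]
    offending <- setdiff(shared, allowed)
    if (!length(offending)) {
      vm <- VectorModel(feats, spacerFeature)
      validObject(vm)
      return(vm)
    }
    # regenerate every non-spacer feature touched by an offending window
    offWin <- IRanges::IRanges(offending, width = k)
    touched <- names(fr)[IRanges::overlapsAny(fr, offWin)]
    touched <- setdiff(touched, spacerFeature)
    if (!length(touched))
      stop("host genome shares a k-mer with the spacer flanks; ",
           "choose a different seed or site")
    for (nm in touched)
      feats[[nm]] <- randomDNA(featureLengths[[nm]])
  }
  stop("could not build a collision-free vector in ", maxIter, " attempts")
}

#' Insert a vector fragment into a genome
#'
#' Emulates integration of partial foreign DNA: the vector substring
#' `[fragStart, fragStart + fragLen - 1]` is inserted so that it begins at
#' genome position `insertPos`.
#'
#' @param genome a [StrainGenome-class] (single contig).
#' @param vector a [VectorModel-class].
#' @param fragStart 1-based start of the fragment on the vector.
#' @param fragLen fragment length in bp (>= 1).
#' @param insertPos 1-based genome position at which the fragment starts
#'   after insertion.
#' @param label label of the modified genome.
#' @return the modified [StrainGenome-class] (length + `fragLen`).
#' @export
insertForeignFragment <- function(genome, vector, fragStart, fragLen,
                                  insertPos,
                                  label = paste0(genome@label, "_insert")) {
  full <- as.character(vectorSequence(vector))
  if (fragLen < 1L)
    stop("'fragLen' must be >= 1")
  if (fragStart < 1L || fragStart + fragLen - 1L > nchar(full))
    stop("fragment outside the vector")
  s <- as.character(genome@sequences[[1L]])
  if (insertPos < 1L || insertPos > nchar(s) + 1L)
    stop("'insertPos' outside the genome")
  frag <- substr(full, fragStart, fragStart + fragLen - 1L)
  s2 <- paste0(substr(s, 1L, insertPos - 1L), frag,
               substr(s, insertPos, nchar(s)))
  seqs <- Biostrings::DNAStringSet(s2)
  names(seqs) <- names(genome@sequences)[1L]
  StrainGenome(label, seqs, genome@snvs)
}

#' Choose a CRISPR target site on a synthetic genome
#'
#' Scans the plus strand for the first NGG PAM after `minStart` and returns
#' the 20-bp protospacer immediately 5' of it.
#'
#' @param genome a [StrainGenome-class].
#' @param minStart smallest admissible protospacer start.
#' @return a [TargetSite-class].
#' @export
chooseTargetSite <- function(genome, minStart = 1000L) {
  s <- as.character(genome@sequences[[1L]])
  L <- nchar(s)
  i <- max(minStart, 21L)
  while (i + 22L <= L) {
    pam <- substr(s, i + 20L, i + 22L)
    if (substr(pam, 2L, 3L) == "GG")
      return(TargetSite(names(genome@sequences)[1L], i, i + 19L, "+", pam))
    i <- i + 1L
  }
  stop("no NGG PAM found after position ", minStart)
}
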