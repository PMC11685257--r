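## Amplicon-level analysis: global alignment, target-site indel calls,
## SNV-based nucleus-of-origin assignment, and in-silico PCR.

#' Primer pair
#'
#' @slot forward,reverse primer sequences (5'->3', each >= 15 bp).
#' @slot maxProduct maximum admissible product length in bp.
#'
#' @export
setClass("PrimerPair",
  representation(forward = "character", reverse = "character",
                 maxProduct = "integer")
)

setValidity("PrimerPair", function(object) {
  if (nchar(object@forward) < 15L || nchar(object@reverse) < 15L)
    return("primers must be >= 15 bp")
  TRUE
})

#' @param forward,reverse,maxProduct see slots.
#' @rdname PrimerPair-class
#' @export
PrimerPair <- function(forward, reverse, maxProduct = 5000L) {
  new("PrimerPair", forward = toupper(forward), reverse = toupper(reverse),
      maxProduct = as.integer(maxProduct))
}

## Shift every indel in a pair of gapped sequences as far left as the
## flanking sequence allows (standard variant left-normalization).  A gap
## run over columns [i..j] preceded by a match column p = i-1 may move one
## column left when the non-gapped base at column j equals the base at
## column p; the rotation pairs the displaced base with column j and
## preserves the alignment score.
leftAlignGaps <- function(ar, aq) {
  r <- strsplit(ar, "", fixed = TRUE)[[1]]
  q <- strsplit(aq, "", fixed = TRUE)[[1]]
  n <- length(r)
  i <- 2L
  while (i <= n) {
    gapInQ <- q[i] == "-"
    gapInR <- r[i] == "-"
    if (!gapInQ && !gapInR) { i <- i + 1L; next }
    j <- i
    while (j < n && (if (gapInQ) q[j + 1L] == "-" else r[j + 1L] == "-"))
      j <- j + 1L
    p <- i - 1L
    lastBase <- if (gapInQ) r[j] else q[j]
    if (p >= 1L && r[p] != "-" && q[p] != "-" && r[p] == q[p] &&
        lastBase == r[p]) {
      if (gapInQ) {
        qseg <- q[p:j]
        q[p:j] <- c(qseg[-1L], qseg[1L])
      } else {
        rseg <- r[p:j]
        r[p:j] <- c(rseg[-1L], rseg[1L])
      }
      i <- max(p, 2L)   # the gap moved left; re-examine from there
    } else {
      i <- j + 1L
    }
  }
  list(ref = paste(r, collapse = ""), query = paste(q, collapse = ""))
}

## Decompose a gapped alignment into operations tiling the reference.
## For insertions refStart = refEnd = the reference base 5' of the
## insertion (0 if inserted before the first base).
alignmentOpsFromStrings <- function(ar, aq) {
  r <- strsplit(ar, "", fixed = TRUE)[[1]]
  q <- strsplit(aq, "", fixed = TRUE)[[1]]
  type <- ifelse(r == "-", "insertion",
          ifelse(q == "-", "deletion",
          ifelse(r == q, "match", "mismatch")))
  rl <- rle(type)
  ncols <- length(r)
  refPos <- cumsum(r != "-")
  qryPos <- cumsum(q != "-")
  endCol <- cumsum(rl$lengths)
  startCol <- endCol - rl$lengths + 1L
  op <- rl$values
  refStart <- integer(length(op)); refEnd <- integer(length(op))
  qryStart <- integer(length(op)); qryEnd <- integer(length(op))
  sq <- character(length(op))
  for (x in seq_along(op)) {
    cs <- startCol[x]; ce <- endCol[x]
    if (op[x] == "insertion") {
      refStart[x] <- refEnd[x] <- if (cs > 1L) refPos[cs - 1L] else 0L
      qryStart[x] <- qryPos[cs]; qryEnd[x] <- qryPos[ce]
      sq[x] <- paste(q[cs:ce], collapse = "")
    } else {
      refStart[x] <- refPos[cs]; refEnd[x] <- refPos[ce]
      if (op[x] == "deletion") {
        qryStart[x] <- qryEnd[x] <- if (cs > 1L) qryPos[cs - 1L] else 0L
        sq[x] <- paste(r[cs:ce], collapse = "")
      } else {
        qryStart[x] <- qryPos[cs]; qryEnd[x] <- qryPos[ce]
        sq[x] <- if (op[x] == "mismatch") paste(q[cs:ce], collapse = "") else ""
      }
    }
  }
  data.frame(op = op, refStart = refStart, refEnd = refEnd,
             queryStart = qryStart, queryEnd = qryEnd,
             length = rl$lengths, seq = sq, stringsAsFactors = FALSE)
}

#' Affine-gap global alignment
#'
#' Optimal global (Needleman-Wunsch/Gotoh) alignment under affine-gap
#' scoring.  Ties break deterministically: a mismatch is preferred over a
#' gap, and a deletion (gap in the query) over an insertion.  Indels are
#' subsequently left-aligned, mirroring common variant-normalization
#' practice, which does not change the score.
#'
#' @param reference,query DNA sequences (character or
#'   [Biostrings::DNAString]); non-empty, at most 20 kb.
#' @param match,mismatch per-base scores (defaults +2 / -3).
#' @param gapOpen score of a length-1 gap (default -6); a gap of length L
#'   scores `gapOpen + (L - 1) * gapExtend`.
#' @param gapExtend per-base extension score (default -1).
#' @return an [AlignmentResult-class].
#' @export
globalAlign <- function(reference, query, match = 2, mismatch = -3,
                        gapOpen = -6, gapExtend = -1) {
  reference <- toupper(as.character(reference))
  query <- toupper(as.character(query))
  if (!nzchar(reference) || !nzchar(query))
    stop("empty sequence")
  if (nchar(reference) > 20000L || nchar(query) > 20000L)
    stop("sequences longer than 20 kb are not supported")
  res <- .affineAlignCpp(reference, query, match, mismatch, gapOpen, gapExtend)
  la <- leftAlignGaps(res$alignedRef, res$alignedQuery)
  new("AlignmentResult", alignedRef = la$ref, alignedQuery = la$query,
      score = res$score, ops = alignmentOpsFromStrings(la$ref, la$query))
}

#' Call the mutation at a CRISPR target site
#'
#' Inspects the protospacer+PAM window (the PAM is included, so
#' PAM-disrupting edits count as target mutations) of an aligned amplicon.
#' A single indel or substitution run overlapping the window is reported
#' with its size and the signed offset of its nearest boundary from the
#' cut site (between protospacer positions 17 and 18); several distinct
#' operations give kind `"complex"`; none gives `"none"`.  Non-reference
#' operations outside the window are listed separately.
#'
#' @param aln an [AlignmentResult-class] whose reference covers the window.
#' @param site a [TargetSite-class] in reference coordinates.
#' @return an [EditCall-class].
#' @export
callTargetMutation <- function(aln, site) {
  win <- targetWindow(site)
  refLen <- sum(aln@ops$length[aln@ops$op != "insertion"])
  if (win[1] < 1L || win[2] > refLen)
    stop("alignment does not span the protospacer+PAM window")
  cut <- cutSiteAfter(site)
  ops <- aln@ops[aln@ops$op != "match", , drop = FALSE]
  if (nrow(ops)) {
    inWin <- ifelse(ops$op == "insertion",
                    ops$refStart >= win[1] - 1L & ops$refStart <= win[2],
                    ops$refStart <= win[2] & ops$refEnd >= win[1])
  } else {
    inWin <- logical(0)
  }
  target <- ops[inWin, , drop = FALSE]
  other <- ops[!inWin, c("op", "refStart", "refEnd", "length", "seq"),
               drop = FALSE]
  if (!nrow(target)) {
    return(new("EditCall", kind = "none", size = 0L, offset = 0L,
               withinTarget = FALSE, otherVariants = other))
  }
  offsetOf <- function(s, e, isIns) {
    if (isIns) {
      # inserted after reference base s
      return(as.integer(s - cut))
    }
    if (e <= cut) return(as.integer(e - cut))
    if (s > cut) return(as.integer(s - cut - 1L) + 1L)
    0L
  }
  offs <- mapply(offsetOf, target$refStart, target$refEnd,
                 target$op == "insertion")
  if (nrow(target) == 1L) {
    kind <- switch(target$op, mismatch = "substitution", target$op)
    size <- target$length
    off <- offs[1L]
  } else {
    kind <- "complex"
    size <- sum(target$length)
    off <- offs[which.min(abs(offs))]
  }
  new("EditCall", kind = kind, size = as.integer(size),
      offset = as.integer(off), withinTarget = TRUE, otherVariants = other)
}

#' Assign the nucleus of origin of an amplicon
#'
#' Genotypes the catalogued SNVs between the donor and recipient parental
#' strains that the alignment covers.  Sites removed by a deletion are
#' excluded from the vote; sites whose query allele matches neither
#' catalogued allele are uninformative.  The call is `recipient` (or
#' `donor`) when every informative site shows that parent's allele,
#' `ambiguous` when both parents are represented, and `uninformative` when
#' no covered site is informative.
#'
#' @param aln an [AlignmentResult-class]; reference coordinates must match
#'   the SNV table's positions.
#' @param snvs data.frame with columns `pos` (1-based reference position),
#'   `donor`, `recipient` (the two alleles; they must differ).
#' @return list with `origin` (one of `"donor"`, `"recipient"`,
#'   `"ambiguous"`, `"uninformative"`) and `calls` (data.frame `pos`,
#'   `allele`, `call`).
#' @export
assignNucleusOrigin <- function(aln, snvs) {
  stopifnot(all(c("pos", "donor", "recipient") %in% names(snvs)))
  if (nrow(snvs) && any(snvs$donor == snvs$recipient))
    stop("donor and recipient alleles must differ")
  refLen <- sum(aln@ops$length[aln@ops$op != "insertion"])
  covered <- snvs[snvs$pos >= 1L & snvs$pos <= refLen, , drop = FALSE]
  if (!nrow(covered))
    stop("no catalogued SNV is covered by the alignment")
  r <- strsplit(aln@alignedRef, "", fixed = TRUE)[[1]]
  q <- strsplit(aln@alignedQuery, "", fixed = TRUE)[[1]]
  refPos <- cumsum(r != "-")
  col <- match(covered$pos, ifelse(r == "-", NA_integer_, refPos))
  allele <- ifelse(is.na(col), NA_character_, q[col])
  deleted <- !is.na(allele) & allele == "-"
  allele[deleted] <- NA_character_
  call <- rep("uninformative", nrow(covered))
  call[!is.na(allele) & allele == covered$donor] <- "donor"
  call[!is.na(allele) & allele == covered$recipient] <- "recipient"
  call[is.na(allele)] <- "excluded"
  informative <- call[call %in% c("donor", "recipient")]
  origin <- if (!length(informative)) "uninformative"
            else if (all(informative == "recipient")) "recipient"
            else if (all(informative == "donor")) "donor"
            else "ambiguous"
  list(origin = origin,
       calls = data.frame(pos = covered$pos, allele = allele, call = call,
                          stringsAsFactors = FALSE))
}

#' In-silico PCR
#'
#' Predicts amplification from exact primer matches: the forward primer
#' must match the template plus strand and the reverse complement of the
#' reverse primer must match downstream of it, with the product no longer
#' than `maxProduct`.  No mismatch tolerance is applied, reproducing the
#' binary presence/absence reading of gel-based genotyping.
#'
#' @param template template sequence (character or
#'   [Biostrings::DNAString]).
#' @param primers a [PrimerPair-class].
#' @return data.frame with columns `start`, `end`, `length`, `product`
#'   (zero rows when no product forms); more than one row raises a
#'   multi-product warning.
#' @export
insilicoPcr <- function(template, primers) {
  validObject(primers)
  s <- toupper(as.character(template))
  subj <- Biostrings::DNAString(s)
  fHits <- Biostrings::start(
    Biostrings::matchPattern(Biostrings::DNAString(primers@forward), subj))
  rcRev <- revcompChar(primers@reverse)
  rHitsIR <- Biostrings::matchPattern(Biostrings::DNAString(rcRev), subj)
  rEnds <- Biostrings::end(rHitsIR)
  rStarts <- Biostrings::start(rHitsIR)
  out <- data.frame(start = integer(0), end = integer(0),
                    length = integer(0), product = character(0),
                    stringsAsFactors = FALSE)
  for (f in fHits) {
    ok <- which(rStarts >= f + nchar(primers@forward) &
                rEnds - f + 1L <= primers@maxProduct)
    for (idx in ok) {
      e <- rEnds[idx]
      out <- rbind(out, data.frame(
        start = f, end = e, length = e - f + 1L,
        product = substr(s, f, e), stringsAsFactors = FALSE))
    }
  }
  if (nrow(out) > 1L)
    warning("multiple products predicted (", nrow(out), ")")
  out
}
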