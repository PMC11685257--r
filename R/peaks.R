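## Peak calling over significant positions, peak classification, and the
## foreign-DNA verdict.

#' Call peaks of significant positions
#'
#' A peak is a maximal run of significant positions with one enrichment
#' direction; runs separated by at most `peakGap` non-significant positions
#' merge.  Adjacent significant positions with opposite directions never
#' merge.
#'
#' @param sig a [SignificanceTrack-class].
#' @param config an [AnalysisConfig-class] (only `peakGap` is used).
#' @return an [IRanges::IRanges] of peaks (coordinates are k-mer window
#'   starts, 1-based inclusive) with metadata columns `maxG`, `direction`,
#'   `meanSample`, `meanControl`.
#' @export
callPeaks <- function(sig, config = AnalysisConfig()) {
  df <- sig@stats
  pos <- df$position[df$significant]
  if (!length(pos)) {
    ir <- IRanges::IRanges()
    S4Vectors::mcols(ir) <- S4Vectors::DataFrame(
      maxG = numeric(0), direction = character(0),
      meanSample = numeric(0), meanControl = numeric(0))
    return(ir)
  }
  dir <- df$direction[df$significant]
  gap <- config@peakGap
  newGrp <- c(TRUE, diff(pos) > gap + 1L | dir[-1L] != dir[-length(dir)])
  grp <- cumsum(newGrp)
  starts <- tapply(pos, grp, min)
  ends <- tapply(pos, grp, max)
  maxG <- tapply(df$G[df$significant], grp, max)
  meanS <- tapply(df$sampleCount[df$significant], grp, mean)
  meanC <- tapply(df$controlCount[df$significant], grp, mean)
  dirs <- tapply(dir, grp, function(d) d[1L])
  ir <- IRanges::IRanges(start = as.integer(starts), end = as.integer(ends))
  S4Vectors::mcols(ir) <- S4Vectors::DataFrame(
    maxG = as.numeric(maxG), direction = as.character(dirs),
    meanSample = as.numeric(meanS), meanControl = as.numeric(meanC))
  ir
}

#' Classify peaks biologically
#'
#' A sample-enriched peak is a foreign-DNA candidate: the edited strain
#' supports vector sequence its wild-type control does not.  A
#' control-enriched peak overlapping the gRNA spacer window is the
#' target-mutation signature: the wild type still carries the intact 20-bp
#' target that the edited strain has lost.  Other control-enriched peaks
#' are left unclassified.  Separately, non-significant regions supported by
#' both tracks are reported as shared endogenous sequence.
#'
#' Peak coordinates are window starts; a window start `p` covers vector
#' bases `p .. p+k-1`, and overlap with the spacer window is computed on
#' those extents.
#'
#' @param peakSet an [IRanges::IRanges] from [callPeaks()].
#' @param sample,control the input [PositionCountTrack-class]s.
#' @param vector optional [VectorModel-class]; its spacer feature supplies
#'   `spacerWin`.
#' @param spacerWin optional [IRanges::IRanges] giving the spacer window in
#'   vector base coordinates (overrides `vector`).
#' @return list with `peaks` (the input ranges plus metadata columns
#'   `class` and `rationale`) and `shared` (an [IRanges::IRanges] of shared
#'   endogenous regions, window-start coordinates).
#' @export
classifyPeaks <- function(peakSet, sample, control, vector = NULL,
                          spacerWin = NULL) {
  k <- sample@k
  if (is.null(spacerWin) && !is.null(vector))
    spacerWin <- spacerWindow(vector)
  m <- S4Vectors::mcols(peakSet)
  n <- length(peakSet)
  cls <- character(n)
  why <- character(n)
  if (n) {
    ext <- IRanges::IRanges(IRanges::start(peakSet),
                            IRanges::end(peakSet) + k - 1L)
    onSpacer <- if (is.null(spacerWin)) rep(FALSE, n)
                else IRanges::overlapsAny(ext, spacerWin)
    for (i in seq_len(n)) {
      if (m$direction[i] == "sample_enriched") {
        cls[i] <- "foreign_candidate"
        why[i] <- "read support in the edited sample exceeds the control: plasmid-derived sequence"
      } else if (onSpacer[i]) {
        cls[i] <- "target_mutation_signature"
        why[i] <- "wild-type-only support at the gRNA spacer: the edited strain lost the intact target"
      } else {
        cls[i] <- "unclassified"
        why[i] <- "control-enriched outside the spacer window"
      }
    }
  }
  m$class <- cls
  m$rationale <- why
  S4Vectors::mcols(peakSet) <- m
  both <- which(sample@counts > 0L & control@counts > 0L)
  shared <- IRanges::reduce(IRanges::IRanges(both, width = 1L))
  if (n) shared <- IRanges::setdiff(shared, peakSet)
  list(peaks = peakSet, shared = shared)
}

#' Render the foreign-DNA verdict
#'
#' The strain is foreign-free iff no peak is classified as
#' `foreign_candidate`; a target-mutation signature at the spacer does not
#' negate the verdict.
#'
#' @param classified list as returned by [classifyPeaks()].
#' @param config the [AnalysisConfig-class] used (echoed in the verdict).
#' @return a [Verdict-class].
#' @export
renderVerdict <- function(classified, config = AnalysisConfig()) {
  pk <- classified$peaks
  cls <- S4Vectors::mcols(pk)$class
  lvls <- c("shared_endogenous", "foreign_candidate",
            "target_mutation_signature", "unclassified")
  cc <- table(factor(cls, levels = lvls))
  cc <- stats::setNames(as.integer(cc), lvls)
  new("Verdict",
      foreignFree = sum(cls == "foreign_candidate") == 0L,
      peaks = pk, sharedRegions = classified$shared,
      classCounts = cc, config = config)
}

#' Editing-efficiency percentage
#'
#' Percentage of resistant strains among those tested, rounded half-up to
#' one decimal (so 15/16 is 93.8, 3/16 is 18.8).
#'
#' @param nResistant number of resistant strains (0 <= nResistant <= nTotal).
#' @param nTotal number of strains tested (> 0).
#' @return percentage with one decimal.
#' @export
summarizeEfficiency <- function(nResistant, nTotal) {
  if (any(nTotal <= 0)) stop("'nTotal' must be > 0")
  if (any(nResistant < 0 | nResistant > nTotal))
    stop("need 0 <= nResistant <= nTotal")
  floor(1000 * nResistant / nTotal + 0.5) / 10
}
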