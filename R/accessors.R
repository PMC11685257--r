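## Accessors and show() methods.

#' @rdname PositionCountTrack-class
#' @export
setMethod("counts", "PositionCountTrack", function(object) object@counts)

#' @rdname PositionCountTrack-class
#' @export
setMethod("totalReads", "PositionCountTrack", function(x) x@totalReads)

#' @rdname VectorModel-class
#' @export
setMethod("vectorSequence", "VectorModel", function(x) {
  unlist(x@features)
})

#' @rdname VectorModel-class
#' @export
setMethod("featureRanges", "VectorModel", function(x) {
  w <- Biostrings::width(x@features)
  ir <- IRanges::IRanges(start = cumsum(c(1L, w[-length(w)])), width = w,
                         names = names(x@features))
  ir
})

#' @rdname VectorModel-class
#' @export
setMethod("spacerWindow", "VectorModel", function(x) {
  featureRanges(x)[x@spacerFeature]
})

#' @rdname Verdict-class
#' @export
setMethod("foreignFree", "Verdict", function(x) x@foreignFree)

#' @rdname Verdict-class
#' @export
setMethod("peaks", "Verdict", function(x) x@peaks)

#' @rdname GTestResult-class
#' @export
setMethod("gStat", "GTestResult", function(x) x@g)

#' @rdname GTestResult-class
#' @export
setMethod("direction", "GTestResult", function(x) x@direction)

#' @rdname GTestResult-class
#' @export
setMethod("isSignificant", "GTestResult", function(x) x@significant)

#' @rdname SignificanceTrack-class
#' @export
setMethod("sigStats", "SignificanceTrack", function(x) x@stats)

#' @rdname AlignmentResult-class
#' @export
setMethod("alignmentOps", "AlignmentResult", function(x) x@ops)

#' @rdname AlignmentResult-class
#' @export
setMethod("score", "AlignmentResult", function(x) x@score)

#' @rdname StrainGenome-class
#' @export
setMethod("snvTable", "StrainGenome", function(x) x@snvs)

setMethod("show", "PositionCountTrack", function(object) {
  cat("PositionCountTrack on '", object@vectorId, "' (k = ", object@k, ")\n",
      "  positions: ", length(object@counts),
      "; nonzero: ", sum(object@counts > 0L),
      "; total reads scanned: ", object@totalReads, "\n", sep = "")
})

setMethod("show", "SignificanceTrack", function(object) {
  nsig <- sum(object@stats$significant)
  cat("SignificanceTrack on '", object@vectorId, "' (k = ", object@k, ")\n",
      "  positions: ", nrow(object@stats),
      "; significant (G > ", format(object@gCritical), "): ", nsig, "\n",
      "  totals: sample ", object@sampleTotal,
      ", control ", object@controlTotal, "\n", sep = "")
})

setMethod("show", "GTestResult", function(object) {
  cat("G = ", format(object@g, digits = 6), " (", object@direction,
      if (object@significant) ", significant" else ", not significant",
      ")\n", sep = "")
})

setMethod("show", "StrainGenome", function(object) {
  cat("StrainGenome '", object@label, "': ",
      length(object@sequences), " contig(s), ",
      sum(Biostrings::width(object@sequences)), " bp, ",
      nrow(object@snvs), " SNV(s) vs progenitor\n", sep = "")
})

setMethod("show", "VectorModel", function(object) {
  cat("VectorModel: ", length(object@features), " features, ",
      sum(Biostrings::width(object@features)), " bp total; spacer = '",
      object@spacerFeature, "'\n", sep = "")
  fr <- featureRanges(object)
  for (i in seq_along(fr))
    cat(sprintf("  %-12s %6d..%6d\n", names(fr)[i],
                IRanges::start(fr)[i], IRanges::end(fr)[i]))
})

setMethod("show", "Verdict", function(object) {
  cat("Foreign-DNA verdict: ",
      if (object@foreignFree) "FOREIGN-FREE" else "FOREIGN DNA DETECTED",
      "\n", sep = "")
  cc <- object@classCounts
  cat("  peaks: ", length(object@peaks), sep = "")
  if (length(cc))
    cat(" (", paste(names(cc), cc, sep = ": ", collapse = ", "), ")", sep = "")
  cat("\n")
  if (length(object@peaks)) {
    m <- S4Vectors::mcols(object@peaks)
    for (i in seq_along(object@peaks))
      cat(sprintf("  [%d..%d] %s, max G = %.3f (%s)\n",
                  IRanges::start(object@peaks)[i],
                  IRanges::end(object@peaks)[i],
                  m$class[i], m$maxG[i], m$direction[i]))
  }
  cat("  shared endogenous regions: ", length(object@sharedRegions),
      "\n", sep = "")
})

setMethod("show", "EditCall", function(object) {
  if (object@kind == "none") {
    cat("EditCall: no mutation in the target window\n")
  } else {
    cat("EditCall: ", object@kind, ", ", object@size, " bp, offset ",
        object@offset, " bp from cut site",
        if (object@withinTarget) " (within target)" else "", "\n", sep = "")
  }
  if (nrow(object@otherVariants))
    cat("  plus ", nrow(object@otherVariants),
        " variant(s) outside the target window\n", sep = "")
})
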