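#' @rdname PositionCountTrack-class
#' @param object,x a transclean object.
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' @rdname VectorModel-class
#' @export
setGeneric("vectorSequence", function(x) standardGeneric("vectorSequence"))

#' @rdname VectorModel-class
#' @export
setGeneric("featureRanges", function(x) standardGeneric("featureRanges"))

#' @rdname VectorModel-class
#' @export
setGeneric("spacerWindow", function(x) standardGeneric("spacerWindow"))

#' @rdname Verdict-class
#' @export
setGeneric("foreignFree", function(x) standardGeneric("foreignFree"))

#' @rdname Verdict-class
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @rdname GTestResult-class
#' @export
setGeneric("gStat", function(x) standardGeneric("gStat"))

#' @rdname GTestResult-class
#' @export
setGeneric("direction", function(x) standardGeneric("direction"))

#' @rdname GTestResult-class
#' @export
setGeneric("isSignificant", function(x) standardGeneric("isSignificant"))

#' @rdname SignificanceTrack-class
#' @export
setGeneric("sigStats", function(x) standardGeneric("sigStats"))

#' @rdname AlignmentResult-class
#' @export
setGeneric("alignmentOps", function(x) standardGeneric("alignmentOps"))

#' @rdname StrainGenome-class
#' @export
setGeneric("snvTable", function(x) standardGeneric("snvTable"))
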