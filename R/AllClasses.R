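## S4 classes for the verification pipeline.  Coordinates are 1-based
## inclusive throughout; track positions are k-mer window starts on the
## vector sequence.

#' Analysis configuration
#'
#' Parameters of the k-mer scan and the per-position G-test.
#'
#' @slot k window length in bp used for the k-mer decomposition (default 20).
#' @slot gCritical critical value on the G statistic; the default 6.634 is
#'   the 0.99 quantile of the chi-squared distribution with 1 df truncated
#'   to three decimals, i.e. significance at the 1% level.
#' @slot alpha nominal significance level (used only when a multiple-testing
#'   adjustment recomputes the critical value).
#' @slot peakGap maximum number of consecutive non-significant positions
#'   merged into a peak (default 0: only adjacent significant window starts
#'   merge).
#' @slot multipleTesting `"none"` (every position tested at `gCritical`) or
#'   `"bonferroni"` (alpha divided by the number of positions with a nonzero
#'   count in either track).
#' @slot williams apply Williams' continuity correction to G (default FALSE;
#'   the fixed critical value 6.634 is conventionally used uncorrected).
#'
#' @export
setClass("AnalysisConfig",
  representation(
    k = "integer",
    gCritical = "numeric",
    alpha = "numeric",
    peakGap = "integer",
    multipleTesting = "character",
    williams = "logical"
  )
)

setValidity("AnalysisConfig", function(object) {
  msg <- character(0)
  if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
    msg <- c(msg, "'k' must be a single integer >= 1")
  if (length(object@gCritical) != 1L || !(object@gCritical > 0))
    msg <- c(msg, "'gCritical' must be a single value > 0")
  if (!(object@alpha > 0 && object@alpha < 1))
    msg <- c(msg, "'alpha' must lie in (0, 1)")
  if (object@peakGap < 0L)
    msg <- c(msg, "'peakGap' must be >= 0")
  if (!object@multipleTesting %in% c("none", "bonferroni"))
    msg <- c(msg, "'multipleTesting' must be \"none\" or \"bonferroni\"")
  if (length(msg)) msg else TRUE
})

#' @param k,gCritical,alpha,peakGap,multipleTesting,williams see slots.
#' @rdname AnalysisConfig-class
#' @export
AnalysisConfig <- function(k = 20L, gCritical = 6.634, alpha = 0.01,
                           peakGap = 0L, multipleTesting = c("none", "bonferroni"),
                           williams = FALSE) {
  new("AnalysisConfig",
      k = as.integer(k), gCritical = as.numeric(gCritical),
      alpha = as.numeric(alpha), peakGap = as.integer(peakGap),
      multipleTesting = match.arg(multipleTesting),
      williams = isTRUE(williams))
}

#' Simulation configuration
#'
#' Full parameterization of a synthetic sequencing experiment: genome size
#' and composition, strain divergence, and the paired-end read model
#' (150-bp reads at 30-fold depth by default, matching a typical short-read
#' resequencing run).
#'
#' @slot genomeLength genome length in bp.
#' @slot gcContent GC fraction in `[0, 1]`.
#' @slot snvRate per-bp substitution probability in `[0, 1)` used when
#'   deriving a second strain from the progenitor.
#' @slot readLength read length in bp (default 150).
#' @slot coverage fold sequencing depth (default 30).
#' @slot errorRate per-base substitution error probability in `[0, 0.1]`.
#' @slot insertMean,insertSd fragment-length model: normal with this mean and
#'   sd, truncated below at `readLength`.
#' @slot seed integer seed; every generator is reproducible given the seed.
#'
#' @export
setClass("SimConfig",
  representation(
    genomeLength = "integer",
    gcContent = "numeric",
    snvRate = "numeric",
    readLength = "integer",
    coverage = "numeric",
    errorRate = "numeric",
    insertMean = "integer",
    insertSd = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@genomeLength < 1L)
    msg <- c(msg, "'genomeLength' must be a positive integer")
  if (object@gcContent < 0 || object@gcContent > 1)
    msg <- c(msg, "'gcContent' must lie in [0, 1]")
  if (object@snvRate < 0 || object@snvRate >= 1)
    msg <- c(msg, "'snvRate' must lie in [0, 1)")
  if (object@readLength < 1L)
    msg <- c(msg, "'readLength' must be >= 1")
  if (object@coverage <= 0)
    msg <- c(msg, "'coverage' must be > 0")
  if (object@errorRate < 0 || object@errorRate > 0.1)
    msg <- c(msg, "'errorRate' must lie in [0, 0.1]")
  if (object@insertMean < object@readLength)
    msg <- c(msg, "'insertMean' must be >= 'readLength'")
  if (object@insertSd < 0)
    msg <- c(msg, "'insertSd' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param genomeLength,gcContent,snvRate,readLength,coverage,errorRate
#'   see slots.
#' @param insertMean,insertSd,seed see slots.
#' @rdname SimConfig-class
#' @export
SimConfig <- function(genomeLength, gcContent = 0.5, snvRate = 0.001,
                      readLength = 150L, coverage = 30, errorRate = 0.001,
                      insertMean = 400L, insertSd = 50, seed = 1L) {
  new("SimConfig",
      genomeLength = as.integer(genomeLength), gcContent = as.numeric(gcContent),
      snvRate = as.numeric(snvRate), readLength = as.integer(readLength),
      coverage = as.numeric(coverage), errorRate = as.numeric(errorRate),
      insertMean = as.integer(insertMean), insertSd = as.numeric(insertSd),
      seed = as.integer(seed))
}

#' CRISPR target site
#'
#' A 20-bp protospacer with its PAM on a host contig.  The Cas9 blunt cut
#' falls between protospacer positions 17 and 18, i.e. 3 bp 5' of the PAM.
#'
#' @slot contig contig identifier.
#' @slot start,end 1-based inclusive protospacer coordinates (width 20).
#' @slot strand `"+"` or `"-"`; the PAM immediately flanks the protospacer
#'   3' on this strand.
#' @slot pam the 3-base PAM sequence (NGG for SpCas9).
#'
#' @export
setClass("TargetSite",
  representation(
    contig = "character",
    start = "integer",
    end = "integer",
    strand = "character",
    pam = "character"
  )
)

setValidity("TargetSite", function(object) {
  msg <- character(0)
  if (object@end - object@start + 1L != 20L)
    msg <- c(msg, "protospacer must be exactly 20 bp")
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "'strand' must be \"+\" or \"-\"")
  if (nchar(object@pam) != 3L)
    msg <- c(msg, "'pam' must be a 3-mer")
  if (length(msg)) msg else TRUE
})

#' @param contig,start,end,strand,pam see slots.
#' @rdname TargetSite-class
#' @export
TargetSite <- function(contig, start, end, strand = "+", pam = "NGG") {
  new("TargetSite", contig = as.character(contig), start = as.integer(start),
      end = as.integer(end), strand = as.character(strand),
      pam = toupper(as.character(pam)))
}

#' Edit specification
#'
#' A programmed mutation at a target site: small indels and substitutions
#' (the typical Cas9 repair outcomes) or a large deletion removing flanking
#' sequence.  `offset` displaces the edit from the cut site (between
#' protospacer positions 17/18).
#'
#' @slot kind one of `"deletion"`, `"insertion"`, `"substitution"`,
#'   `"large_deletion"`.
#' @slot size edit size in bp (>= 1).
#' @slot offset signed displacement in bp from the cut site.
#' @slot insertedSeq bases to insert (insertions only; `""` otherwise).
#'
#' @export
setClass("EditSpec",
  representation(
    kind = "character",
    size = "integer",
    offset = "integer",
    insertedSeq = "character"
  )
)

setValidity("EditSpec", function(object) {
  msg <- character(0)
  if (!object@kind %in% c("deletion", "insertion", "substitution", "large_deletion"))
    msg <- c(msg, "unknown edit kind")
  if (object@size < 1L)
    msg <- c(msg, "'size' must be >= 1")
  if (object@kind == "insertion" && nchar(object@insertedSeq) != object@size)
    msg <- c(msg, "'insertedSeq' length must equal 'size' for insertions")
  if (length(msg)) msg else TRUE
})

#' @param kind,size,offset,insertedSeq see slots.
#' @rdname EditSpec-class
#' @export
EditSpec <- function(kind, size, offset = 0L, insertedSeq = "") {
  size <- as.integer(size)
  if (kind == "insertion" && nzchar(insertedSeq) && missing(size))
    size <- nchar(insertedSeq)
  new("EditSpec", kind = as.character(kind), size = size,
      offset = as.integer(offset), insertedSeq = toupper(insertedSeq))
}

#' Strain genome
#'
#' One haploid (monokaryon) genome, optionally annotated with the SNVs that
#' separate it from its progenitor strain.  Applying `snvs` to the
#' progenitor reproduces `sequences` exactly; SNV coordinates refer to the
#' genome *before* any structural edit.
#'
#' @slot label strain label (e.g. `"donor"`, `"recipient"`).
#' @slot sequences a [Biostrings::DNAStringSet] of contigs.
#' @slot snvs data.frame with columns `contig`, `pos` (1-based), `ref`
#'   (progenitor allele), `alt` (this strain's allele).
#'
#' @export
setClass("StrainGenome",
  representation(
    label = "character",
    sequences = "DNAStringSet",
    snvs = "data.frame"
  )
)

setValidity("StrainGenome", function(object) {
  msg <- character(0)
  if (!all(c("contig", "pos", "ref", "alt") %in% names(object@snvs)))
    msg <- c(msg, "'snvs' must have columns contig, pos, ref, alt")
  if (nrow(object@snvs) && any(object@snvs$ref == object@snvs$alt))
    msg <- c(msg, "SNV ref and alt alleles must differ")
  if (length(msg)) msg else TRUE
})

#' @param label,sequences,snvs see slots.
#' @rdname StrainGenome-class
#' @export
StrainGenome <- function(label, sequences,
                         snvs = data.frame(contig = character(0),
                                           pos = integer(0),
                                           ref = character(0),
                                           alt = character(0))) {
  if (is.character(sequences))
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  new("StrainGenome", label = as.character(label), sequences = sequences,
      snvs = as.data.frame(snvs))
}

#' Transformation vector model
#'
#' An ordered set of named vector features (origin, resistance genes, Cas9
#' cassette, U6-driven gRNA spacer, ...) whose concatenation is the full
#' vector sequence.  Exactly one feature, the spacer, is identical to a
#' host protospacer; by construction it is the only >= k-bp exact match
#' between vector and host genome, so a wild-type control only supports the
#' spacer position of the vector.
#'
#' @slot features named [Biostrings::DNAStringSet], in vector order.
#' @slot spacerFeature name of the feature carrying the 20-bp gRNA spacer.
#'
#' @export
setClass("VectorModel",
  representation(
    features = "DNAStringSet",
    spacerFeature = "character"
  )
)

setValidity("VectorModel", function(object) {
  msg <- character(0)
  if (is.null(names(object@features)) || anyDuplicated(names(object@features)))
    msg <- c(msg, "'features' must have unique names")
  if (sum(names(object@features) == object@spacerFeature) != 1L)
    msg <- c(msg, "exactly one feature must be the spacer feature")
  if (length(msg)) msg else TRUE
})

#' @param features,spacerFeature see slots.
#' @rdname VectorModel-class
#' @export
VectorModel <- function(features, spacerFeature) {
  if (is.character(features)) {
    nm <- names(features)
    features <- Biostrings::DNAStringSet(toupper(features))
    names(features) <- nm
  }
  new("VectorModel", features = features,
      spacerFeature = as.character(spacerFeature))
}

#' k-mer index of a vector sequence
#'
#' Maps each canonical k-mer (lexicographic minimum of a window and its
#' reverse complement, so both strands collapse to one key) of the vector
#' to the 1-based window start positions it occupies.  Windows containing
#' non-ACGT bases are skipped.
#'
#' @slot k window length.
#' @slot vectorLength vector length in bp.
#' @slot vectorId identifier of the indexed sequence.
#' @slot table data.frame with columns `kmer` (canonical) and `pos`.
#'
#' @export
setClass("KmerIndex",
  representation(
    k = "integer",
    vectorLength = "integer",
    vectorId = "character",
    table = "data.frame"
  )
)

#' Per-position read-count track
#'
#' For every k-mer window start of the vector, the number of scanned reads
#' containing that window's canonical k-mer (each read counted at most once
#' per position), plus the total number of reads scanned.  This is the unit
#' of evidence the G-test compares between sample and control.
#'
#' @slot counts integer vector of length `vectorLength - k + 1`.
#' @slot totalReads number of reads scanned.
#' @slot k window length used.
#' @slot vectorId identifier of the indexed vector.
#'
#' @export
setClass("PositionCountTrack",
  representation(
    counts = "integer",
    totalReads = "integer",
    k = "integer",
    vectorId = "character"
  )
)

setValidity("PositionCountTrack", function(object) {
  msg <- character(0)
  if (any(object@counts < 0L))
    msg <- c(msg, "counts must be >= 0")
  if (any(object@counts > object@totalReads))
    msg <- c(msg, "no count may exceed totalReads")
  if (length(msg)) msg else TRUE
})

#' @param counts,totalReads,k,vectorId see slots.
#' @rdname PositionCountTrack-class
#' @export
PositionCountTrack <- function(counts, totalReads, k = 20L, vectorId = "vector") {
  new("PositionCountTrack", counts = as.integer(counts),
      totalReads = as.integer(totalReads), k = as.integer(k),
      vectorId = as.character(vectorId))
}

#' G-test result for one 2x2 table
#'
#' @slot g the G statistic (>= 0).
#' @slot direction `"sample_enriched"`, `"control_enriched"` or `"none"`.
#' @slot significant TRUE iff G exceeds the configured critical value.
#'
#' @export
setClass("GTestResult",
  representation(g = "numeric", direction = "character", significant = "logical")
)

setValidity("GTestResult", function(object) {
  msg <- character(0)
  if (object@g < 0) msg <- c(msg, "G must be >= 0")
  if (object@g == 0 && object@direction != "none")
    msg <- c(msg, "G = 0 implies direction \"none\"")
  if (object@significant && object@direction == "none")
    msg <- c(msg, "a significant result must have a direction")
  if (length(msg)) msg else TRUE
})

#' Per-position significance track
#'
#' Result of applying the G-test at every vector position of a sample
#' track against a control track.
#'
#' @slot stats data.frame with columns `position`, `sampleCount`,
#'   `controlCount`, `G`, `direction`, `significant`.
#' @slot sampleTotal,controlTotal total reads of the two input tracks.
#' @slot gCritical effective critical value used (after any
#'   multiple-testing adjustment).
#' @slot k,vectorId inherited from the input tracks.
#'
#' @export
setClass("SignificanceTrack",
  representation(
    stats = "data.frame",
    sampleTotal = "integer",
    controlTotal = "integer",
    gCritical = "numeric",
    k = "integer",
    vectorId = "character"
  )
)

#' Target-site edit call
#'
#' The mutation found in the protospacer+PAM window of an aligned amplicon.
#'
#' @slot kind `"none"`, `"deletion"`, `"insertion"`, `"substitution"` or
#'   `"complex"` (several distinct operations in the window).
#' @slot size affected bases in bp (0 for `"none"`).
#' @slot offset signed distance in bp of the edit's nearest boundary from
#'   the cut site (0 when the edit spans the cut).
#' @slot withinTarget TRUE iff the call overlaps the protospacer+PAM window.
#' @slot otherVariants data.frame of non-reference operations outside the
#'   target window (op, refStart, refEnd, length, seq).
#'
#' @export
setClass("EditCall",
  representation(
    kind = "character",
    size = "integer",
    offset = "integer",
    withinTarget = "logical",
    otherVariants = "data.frame"
  )
)

setValidity("EditCall", function(object) {
  if (object@kind == "none" && object@size != 0L)
    return("kind \"none\" implies size 0")
  TRUE
})

#' Global alignment result
#'
#' Affine-gap global (Needleman-Wunsch/Gotoh) alignment of a query against
#' a reference, with indels left-aligned.
#'
#' @slot alignedRef,alignedQuery gapped sequences (`-` for gaps).
#' @slot score alignment score.
#' @slot ops data.frame of edit operations tiling the reference: columns
#'   `op` (match/mismatch/insertion/deletion), `refStart`, `refEnd`,
#'   `queryStart`, `queryEnd`, `length`, `seq` (inserted or deleted bases).
#'
#' @export
setClass("AlignmentResult",
  representation(
    alignedRef = "character",
    alignedQuery = "character",
    score = "numeric",
    ops = "data.frame"
  )
)

setValidity("AlignmentResult", function(object) {
  if (nchar(object@alignedRef) != nchar(object@alignedQuery))
    return("aligned sequences must have equal length")
  TRUE
})

#' Foreign-DNA verdict
#'
#' The end point of the pipeline: the strain is foreign-free iff no peak is
#' classified as a foreign candidate.  A control-enriched peak at the gRNA
#' spacer (the target-mutation signature of a successful edit) does not
#' negate the verdict.
#'
#' @slot foreignFree logical verdict.
#' @slot peaks [IRanges::IRanges] of classified peaks with metadata columns
#'   `maxG`, `direction`, `meanSample`, `meanControl`, `class`, `rationale`.
#' @slot sharedRegions [IRanges::IRanges] of non-significant regions
#'   supported by both tracks (shared endogenous sequence).
#' @slot classCounts named integer vector of peak-class counts.
#' @slot config the [AnalysisConfig-class] used.
#'
#' @export
setClass("Verdict",
  representation(
    foreignFree = "logical",
    peaks = "IRanges",
    sharedRegions = "IRanges",
    classCounts = "integer",
    config = "AnalysisConfig"
  )
)

#' Pipeline run configuration
#'
#' File-level inputs and parameters for [runPipeline()].
#'
#' @slot vectorFasta path to the vector FASTA.
#' @slot sampleReads,controlReads paths to FASTQ/FASTA read files
#'   (optionally gzipped); multiple files are merged.
#' @slot featuresTsv optional vector feature table (name, start, end, strand).
#' @slot spacerFeature name of the gRNA spacer feature (`NA` to skip
#'   spacer-aware classification).
#' @slot outDir output directory for the report bundle.
#' @slot analysis an [AnalysisConfig-class].
#'
#' @export
setClass("RunConfig",
  representation(
    vectorFasta = "character",
    sampleReads = "character",
    controlReads = "character",
    featuresTsv = "character",
    spacerFeature = "character",
    outDir = "character",
    analysis = "AnalysisConfig"
  )
)

#' @param vectorFasta,sampleReads,controlReads,featuresTsv,spacerFeature
#'   see slots.
#' @param outDir,analysis see slots.
#' @rdname RunConfig-class
#' @export
RunConfig <- function(vectorFasta, sampleReads, controlReads,
                      featuresTsv = NA_character_,
                      spacerFeature = NA_character_,
                      outDir = ".", analysis = AnalysisConfig()) {
  new("RunConfig", vectorFasta = vectorFasta, sampleReads = sampleReads,
      controlReads = controlReads, featuresTsv = as.character(featuresTsv),
      spacerFeature = as.character(spacerFeature), outDir = outDir,
      analysis = analysis)
}

#' Report bundle
#'
#' Everything one pipeline run produces: the verdict, the significance
#' track, peaks, output paths, and a provenance block sufficient to re-run
#' the deterministic stages bit-identically.
#'
#' @slot verdict a [Verdict-class].
#' @slot significance a [SignificanceTrack-class].
#' @slot sampleTrack,controlTrack the input [PositionCountTrack-class]s.
#' @slot paths named character vector of files written.
#' @slot provenance list (config echo, package version).
#'
#' @export
setClass("ReportBundle",
  representation(
    verdict = "Verdict",
    significance = "SignificanceTrack",
    sampleTrack = "PositionCountTrack",
    controlTrack = "PositionCountTrack",
    paths = "character",
    provenance = "list"
  )
)
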