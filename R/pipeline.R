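## The umbrella pipeline (scan -> test -> peaks -> verdict) and the
## end-to-end synthetic experiment generator.

#' Run the full verification pipeline
#'
#' Scans sample and control read sets against the vector k-mer index,
#' applies the per-position G-test, calls and classifies peaks, renders
#' the foreign-DNA verdict, and writes the report bundle
#' (`sample_track.tsv`, `control_track.tsv`, `significance.tsv`,
#' `peaks.tsv`, `verdict.json`) into `outDir`.  The run is a pure function
#' of its inputs and configuration.
#'
#' @param config a [RunConfig-class].
#' @return a [ReportBundle-class].
#' @export
runPipeline <- function(config) {
  ac <- config@analysis
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  vec <- stage("read_vector", readSequences(config@vectorFasta))
  idx <- stage("index", buildKmerIndex(vec, ac))
  scanFiles <- function(paths) {
    tracks <- lapply(paths, function(p) scanReads(readSequences(p), idx))
    combineTracks(tracks)
  }
  sTrack <- stage("scan_sample", scanFiles(config@sampleReads))
  cTrack <- stage("scan_control", scanFiles(config@controlReads))
  sig <- stage("test", testTrack(sTrack, cTrack, ac))
  pk <- stage("peaks", callPeaks(sig, ac))
  spacerWin <- NULL
  if (!is.na(config@featuresTsv) && !is.na(config@spacerFeature)) {
    feats <- stage("features", readVectorFeatures(config@featuresTsv))
    row <- feats[feats$name == config@spacerFeature, , drop = FALSE]
    if (nrow(row) != 1L)
      stop("stage 'features': spacer feature '", config@spacerFeature,
           "' not found exactly once")
    spacerWin <- IRanges::IRanges(row$start, row$end)
  }
  classified <- stage("classify",
    classifyPeaks(pk, sTrack, cTrack, spacerWin = spacerWin))
  verdict <- renderVerdict(classified, ac)

  dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    sample_track = file.path(config@outDir, "sample_track.tsv"),
    control_track = file.path(config@outDir, "control_track.tsv"),
    significance = file.path(config@outDir, "significance.tsv"),
    peaks = file.path(config@outDir, "peaks.tsv"),
    verdict = file.path(config@outDir, "verdict.json"))
  writeTrack(sTrack, paths[["sample_track"]])
  writeTrack(cTrack, paths[["control_track"]])
  writeSignificance(sig, paths[["significance"]])
  writePeaks(classified$peaks, paths[["peaks"]])
  writeVerdict(verdict, paths[["verdict"]])

  new("ReportBundle", verdict = verdict, significance = sig,
      sampleTrack = sTrack, controlTrack = cTrack, paths = paths,
      provenance = list(
        package = "transclean",
        version = as.character(packageVersion("transclean")),
        analysis = list(k = ac@k, gCritical = ac@gCritical,
                        alpha = ac@alpha, peakGap = ac@peakGap,
                        multipleTesting = ac@multipleTesting,
                        williams = ac@williams),
        inputs = list(vector = config@vectorFasta,
                      sample = config@sampleReads,
                      control = config@controlReads)))
}

#' Simulate a complete editing experiment
#'
#' Generates, from one configuration, every input the verification
#' pipeline needs: a donor progenitor genome, a recipient strain derived
#' from it by scattered SNVs (the protospacer+PAM window is protected so
#' both strains carry an editable target), a transformation vector sharing
#' exactly the 20-bp spacer with the host, an edited recipient carrying an
#' indel at the cut site, optionally a foreign vector fragment integrated
#' into the edited genome, and paired-end reads for the edited strain
#' (sample) and the unedited recipient (wild-type control).
#'
#' @param config a [SimConfig-class]; its `seed` drives every stage.
#' @param edit an [EditSpec-class] applied to the recipient at the chosen
#'   target site (default: a 2-bp deletion at the cut).
#' @param foreignLen length in bp of a vector fragment (taken from inside
#'   the `hph` marker) inserted into the edited genome; 0 for none.
#' @param featureLengths vector layout (see [buildVector()]).
#' @param outDir optional directory; when given, FASTA/FASTQ/TSV files for
#'   every artefact are written there.
#' @return list with elements `donor`, `recipient`, `edited`, `site`,
#'   `vector`, `sampleReads`, `controlReads`, and (when `outDir` is given)
#'   `paths`.
#' @export
simulateExperiment <- function(config, edit = EditSpec("deletion", 2L),
                               foreignLen = 0L,
                               featureLengths = defaultVectorFeatures(),
                               outDir = NULL) {
  validObject(config)
  donor <- generateProgenitorGenome(config, label = "donor")
  site <- chooseTargetSite(donor, minStart = max(1000L,
                           as.integer(config@genomeLength * 0.02)))
  protect <- IRanges::IRanges(site@start, site@end + 3L)
  recipient <- deriveStrain(donor, config@snvRate, protect,
                            seed = config@seed + 1L, label = "recipient")
  vector <- buildVector(featureLengths, recipient, site,
                        seed = config@seed + 2L)
  edited <- applyEdit(recipient, site, edit, label = "edited")
  if (foreignLen > 0L) {
    fr <- featureRanges(vector)
    hph <- fr["hph"]
    fragStart <- IRanges::start(hph) + 100L
    if (fragStart + foreignLen - 1L > IRanges::end(hph))
      fragStart <- IRanges::start(hph)
    insertPos <- as.integer(
      sum(Biostrings::width(edited@sequences)) %/% 3L)
    edited <- insertForeignFragment(edited, vector, fragStart, foreignLen,
                                    insertPos, label = "edited_insert")
  }
  sampleReads <- simulateReads(edited, config, seed = config@seed + 3L)
  controlReads <- simulateReads(recipient, config, seed = config@seed + 4L)
  out <- list(donor = donor, recipient = recipient, edited = edited,
              site = site, vector = vector,
              sampleReads = sampleReads, controlReads = controlReads)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      donor = file.path(outDir, "donor.fasta"),
      recipient = file.path(outDir, "recipient.fasta"),
      edited = file.path(outDir, "edited.fasta"),
      vector = file.path(outDir, "vector.fasta"),
      features = file.path(outDir, "vector_features.tsv"),
      snvs = file.path(outDir, "snvs.tsv"))
    writeFasta(donor, paths[["donor"]])
    writeFasta(recipient, paths[["recipient"]])
    writeFasta(edited, paths[["edited"]])
    writeFasta(vector, paths[["vector"]])
    writeVectorFeatures(vector, paths[["features"]])
    writeSnvTable(recipient@snvs, paths[["snvs"]])
    sp <- writeReadsFastq(sampleReads, file.path(outDir, "sample"))
    cp <- writeReadsFastq(controlReads, file.path(outDir, "control"))
    paths <- c(paths, sample_R1 = sp[1L], sample_R2 = sp[2L],
               control_R1 = cp[1L], control_R2 = cp[2L])
    out$paths <- paths
  }
  out
}
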