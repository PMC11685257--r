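test_that("sequence reading auto-detects FASTA/FASTQ and handles gzip", {
  set.seed(40)
  d <- tempfile(); dir.create(d)
  fa <- file.path(d, "two.fasta")
  writeLines(c(">s1", "acgtacgtacgt", ">s2", "GGGTTTAAACCC"), fa)
  x <- readSequences(fa)
  expect_identical(names(x), c("s1", "s2"))
  expect_identical(as.character(x[[1]]), "ACGTACGTACGT")

  fq <- file.path(d, "reads.fastq")
  writeLines(c("@r1", "ACGTACGT", "+", "IIIIIIII",
               "@r2", "TTTTCCCC", "+", "IIIIIIII"), fq)
  plain <- readSequences(fq)
  gz <- file.path(d, "reads.fastq.gz")
  con <- gzfile(gz, "wb"); writeLines(readLines(fq), con); close(con)
  zipped <- readSequences(gz)
  expect_identical(as.character(plain), as.character(zipped))

  bad <- file.path(d, "trunc.fastq")
  writeLines(c("@r1", "ACGT", "+"), bad)
  expect_error(readSequences(bad), "truncated.*r1")
  empty <- file.path(d, "empty.fa")
  file.create(empty)
  expect_error(readSequences(empty), "empty")
  expect_error(readSequences(file.path(d, "nope.fa")), "no such file")
})

test_that("track, significance and verdict artifacts round-trip", {
  set.seed(41)
  vec <- randomDNA(150)
  idx <- buildKmerIndex(vec, vectorId = "vecX")
  reads <- vapply(1:25, function(i) randomReadFrom(vec, 40), "")
  tr <- scanReads(reads, idx)
  d <- tempfile(); dir.create(d)

  tp <- file.path(d, "track.tsv")
  writeTrack(tr, tp)
  tr2 <- readTrack(tp)
  expect_identical(counts(tr2), counts(tr))
  expect_identical(totalReads(tr2), totalReads(tr))
  expect_identical(tr2@vectorId, "vecX")
  expect_identical(tr2@k, 20L)

  ctl <- scanReads(vapply(1:25, function(i) randomReadFrom(vec, 40), ""), idx)
  sig <- testTrack(tr, ctl)
  sp <- file.path(d, "sig.tsv")
  writeSignificance(sig, sp)
  sig2 <- readSignificance(sp)
  expect_equal(sigStats(sig2)$G, sigStats(sig)$G, tolerance = 1e-12)
  expect_identical(sigStats(sig2)$significant, sigStats(sig)$significant)
  expect_identical(sig2@sampleTotal, sig@sampleTotal)

  cl <- classifyPeaks(callPeaks(sig), tr, ctl)
  v <- renderVerdict(cl)
  vp <- file.path(d, "verdict.json")
  writeVerdict(v, vp)
  back <- readVerdict(vp)
  expect_identical(back$foreign_free, foreignFree(v))
  expect_identical(length(back$peaks), length(peaks(v)))
  expect_identical(back$config$g_critical, 6.634)
})

test_that("SNV, feature and primer tables round-trip", {
  d <- tempfile(); dir.create(d)
  snvs <- data.frame(contig = "chr1", pos = c(10L, 99L), ref = c("A", "G"),
                     alt = c("T", "C"), stringsAsFactors = FALSE)
  sp <- file.path(d, "snv.tsv")
  writeSnvTable(snvs, sp)
  expect_identical(readSnvTable(sp), snvs)

  set.seed(42)
  host <- generateProgenitorGenome(SimConfig(genomeLength = 6000L, seed = 1L))
  site <- chooseTargetSite(host, minStart = 500L)
  vm <- buildVector(c(a = 100L, gRNA_spacer = 20L, b = 50L), host, site)
  fp <- file.path(d, "features.tsv")
  writeVectorFeatures(vm, fp)
  feats <- readVectorFeatures(fp)
  expect_identical(feats$name, c("a", "gRNA_spacer", "b"))
  expect_identical(feats$start, c(1L, 101L, 121L))
  expect_identical(feats$end, c(100L, 120L, 170L))

  pp <- file.path(d, "primers.tsv")
  writeLines(c("name\tforward\treverse\tmax_product",
               paste("pyrG", strrep("ACGT", 5), strrep("TTGC", 5), 3000,
                     sep = "\t")), pp)
  prs <- readPrimerPairs(pp)
  expect_identical(names(prs), "pyrG")
  expect_identical(prs$pyrG@maxProduct, 3000L)
})

test_that("the pipeline run is reproducible and writes a coherent bundle", {
  cfg <- SimConfig(genomeLength = 15000L, errorRate = 0, seed = 21L)
  d <- tempfile()
  ex <- simulateExperiment(cfg, outDir = d)
  rc <- RunConfig(
    vectorFasta = ex$paths[["vector"]],
    sampleReads = unname(ex$paths[c("sample_R1", "sample_R2")]),
    controlReads = unname(ex$paths[c("control_R1", "control_R2")]),
    featuresTsv = ex$paths[["features"]],
    spacerFeature = "gRNA_spacer",
    outDir = file.path(d, "out1"))
  rb <- runPipeline(rc)
  expect_true(foreignFree(rb@verdict))
  expect_true(all(file.exists(rb@paths)))
  expect_identical(totalReads(rb@sampleTrack),
                   2L * length(ex$sampleReads$mate1))

  rc2 <- rc; rc2@outDir <- file.path(d, "out2")
  rb2 <- runPipeline(rc2)
  for (nm in names(rb@paths))
    expect_identical(readLines(rb@paths[[nm]]), readLines(rb2@paths[[nm]]))

  # with an integrated vector fragment the verdict flips and the peak
  # falls inside the hph marker
  ex3 <- simulateExperiment(cfg, foreignLen = 300L,
                            outDir = file.path(d, "sim3"))
  rc3 <- RunConfig(
    vectorFasta = ex3$paths[["vector"]],
    sampleReads = unname(ex3$paths[c("sample_R1", "sample_R2")]),
    controlReads = unname(ex3$paths[c("control_R1", "control_R2")]),
    featuresTsv = ex3$paths[["features"]],
    spacerFeature = "gRNA_spacer",
    outDir = file.path(d, "out3"))
  rb3 <- runPipeline(rc3)
  expect_false(foreignFree(rb3@verdict))
  pk <- peaks(rb3@verdict)
  fc <- pk[S4Vectors::mcols(pk)$class == "foreign_candidate"]
  expect_gt(length(fc), 0L)
  hph <- featureRanges(ex3$vector)["hph"]
  expect_true(all(IRanges::overlapsAny(fc, hph)))

  # stage errors carry the stage name
  rcBad <- rc; rcBad@vectorFasta <- file.path(d, "missing.fa")
  expect_error(runPipeline(rcBad), "read_vector")
})
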