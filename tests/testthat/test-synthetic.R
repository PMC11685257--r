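test_that("genome generation is seed-deterministic and honours GC content", {
  cfg <- SimConfig(genomeLength = 10000L, seed = 7L)
  g1 <- generateProgenitorGenome(cfg)
  g2 <- generateProgenitorGenome(cfg)
  expect_identical(as.character(g1@sequences), as.character(g2@sequences))
  g3 <- generateProgenitorGenome(SimConfig(genomeLength = 10000L, seed = 8L))
  expect_false(identical(as.character(g1@sequences),
                         as.character(g3@sequences)))

  at <- generateProgenitorGenome(SimConfig(genomeLength = 2000L,
                                           gcContent = 0, seed = 1L))
  expect_true(grepl("^[AT]+$", as.character(at@sequences[[1]])))

  expect_error(SimConfig(genomeLength = 0L), "positive")
})

test_that("derived strains record SNVs that reproduce the derived sequence", {
  cfg <- SimConfig(genomeLength = 20000L, seed = 3L)
  prog <- generateProgenitorGenome(cfg)
  der <- deriveStrain(prog, 0.002, seed = 10L)
  snvs <- snvTable(der)
  expect_gt(nrow(snvs), 0)
  s <- strsplit(as.character(prog@sequences[[1]]), "")[[1]]
  expect_identical(paste(s[snvs$pos], collapse = ""),
                   paste(snvs$ref, collapse = ""))
  s[snvs$pos] <- snvs$alt
  expect_identical(paste(s, collapse = ""),
                   as.character(der@sequences[[1]]))
  expect_true(all(snvs$ref != snvs$alt))
})

test_that("SNV counts follow the binomial law over seeds", {
  cfg <- SimConfig(genomeLength = 100000L, seed = 2L)
  prog <- generateProgenitorGenome(cfg)
  n <- vapply(1:20, function(s)
    nrow(snvTable(deriveStrain(prog, 0.001, seed = s))), integer(1))
  mu <- 100000 * 0.001
  sdv <- sqrt(100000 * 0.001 * 0.999)
  expect_true(all(abs(n - mu) < 3 * sdv))
  # and the mean of 20 draws is well inside the law
  expect_lt(abs(mean(n) - mu), 3 * sdv / sqrt(20))
})

test_that("rate zero and protected windows behave as specified", {
  cfg <- SimConfig(genomeLength = 5000L, seed = 4L)
  prog <- generateProgenitorGenome(cfg)
  same <- deriveStrain(prog, 0, seed = 1L)
  expect_identical(as.character(same@sequences), as.character(prog@sequences))
  expect_identical(nrow(snvTable(same)), 0L)
  expect_error(deriveStrain(prog, 1.0, seed = 1L), "snvRate")

  win <- IRanges::IRanges(2001, 2023)
  for (s in 1:10) {
    d <- deriveStrain(prog, 0.05, protectedWindows = win, seed = s)
    expect_false(any(snvTable(d)$pos >= 2001 & snvTable(d)$pos <= 2023))
  }
})

test_that("edits change genome length as specified", {
  cfg <- SimConfig(genomeLength = 3000L, seed = 5L)
  g <- generateProgenitorGenome(cfg)
  site <- chooseTargetSite(g, minStart = 500L)
  L <- nchar(as.character(g@sequences[[1]]))

  del <- applyEdit(g, site, EditSpec("deletion", 13L))
  expect_identical(nchar(as.character(del@sequences[[1]])), L - 13L)

  ins <- applyEdit(g, site, EditSpec("insertion", 1L, insertedSeq = "A"))
  expect_identical(nchar(as.character(ins@sequences[[1]])), L + 1L)

  sub <- applyEdit(g, site, EditSpec("substitution", 2L))
  s2 <- as.character(sub@sequences[[1]])
  expect_identical(nchar(s2), L)
  orig <- strsplit(as.character(g@sequences[[1]]), "")[[1]]
  expect_identical(sum(orig != strsplit(s2, "")[[1]]), 2L)

  offsite <- TargetSite(site@contig, L - 25L, L - 6L, "+", "AGG")
  expect_error(applyEdit(g, offsite, EditSpec("deletion", 50L)), "past")
})

test_that("vector construction yields the exact feature sum and a unique spacer", {
  expect_identical(sum(defaultVectorFeatures()), 9167L)

  cfg <- SimConfig(genomeLength = 8000L, seed = 6L)
  host <- generateProgenitorGenome(cfg)
  site <- chooseTargetSite(host, minStart = 1000L)
  lens <- c(featA = 300L, gRNA_spacer = 20L, featB = 400L)
  vm <- buildVector(lens, host, site, seed = 1L)
  full <- as.character(vectorSequence(vm))
  expect_identical(nchar(full), 720L)
  expect_identical(IRanges::start(spacerWindow(vm)), 301L)

  # exhaustive canonical k-mer intersection is exactly the spacer window
  hostK <- canonicalKmers(substring(as.character(host@sequences[[1]]),
                                    1:(8000 - 19), 20:8000))
  vecK <- canonicalKmers(substring(full, 1:(720 - 19), 20:720))
  shared <- which(vecK %in% hostK)
  expect_identical(shared, 301L)

  expect_error(buildVector(c(a = 10L, gRNA_spacer = 21L), host, site,
                           spacerFeature = "gRNA_spacer"), "20 bp")
  expect_error(buildVector(c(gRNA_spacer = 20L, gRNA_spacer = 20L),
                           host, site), "exactly one")
})

test_that("foreign fragments are inserted verbatim and leave the control alone", {
  cfg <- SimConfig(genomeLength = 8000L, seed = 9L)
  host <- generateProgenitorGenome(cfg)
  site <- chooseTargetSite(host, minStart = 1000L)
  vm <- buildVector(c(featA = 200L, gRNA_spacer = 20L, featB = 200L),
                    host, site, seed = 2L)
  full <- as.character(vectorSequence(vm))
  mod <- insertForeignFragment(host, vm, 50L, 20L, 4000L)
  ms <- as.character(mod@sequences[[1]])
  expect_identical(nchar(ms), 8020L)
  expect_identical(substr(ms, 4000, 4019), substr(full, 50, 69))
  expect_error(insertForeignFragment(host, vm, 50L, 0L, 4000L), "fragLen")
  expect_error(insertForeignFragment(host, vm, 500L, 20L, 4000L), "vector")

  # inserting into the sample genome does not touch a control scan
  idx <- buildKmerIndex(full)
  ctrl <- vapply(1:30, function(i)
    randomReadFrom(as.character(host@sequences[[1]]), 50L), "")
  before <- counts(scanReads(ctrl, idx))
  invisible(insertForeignFragment(host, vm, 50L, 20L, 4000L))
  expect_identical(counts(scanReads(ctrl, idx)), before)
})

test_that("read simulation has the right pair count and exact error-free reads", {
  cfg <- SimConfig(genomeLength = 20000L, errorRate = 0, coverage = 30,
                   seed = 12L)
  g <- generateProgenitorGenome(cfg)
  pairs <- simulateReads(g, cfg)
  expect_identical(length(pairs$mate1), 2000L)   # 30 * 20000 / (2 * 150)
  expect_identical(length(pairs$mate2), 2000L)
  expect_true(all(Biostrings::width(pairs$mate1) == 150L))

  s <- as.character(g@sequences[[1]])
  some <- sample(2000L, 100L)
  for (i in some) {
    m1 <- as.character(pairs$mate1[[i]])
    m2 <- as.character(pairs$mate2[[i]])
    expect_true(grepl(m1, s, fixed = TRUE) ||
                grepl(revcompChar(m1), s, fixed = TRUE))
    expect_true(grepl(revcompChar(m2), s, fixed = TRUE))
  }

  pairs2 <- simulateReads(g, cfg)
  expect_identical(as.character(pairs$mate1), as.character(pairs2$mate1))
  expect_identical(as.character(pairs$mate2), as.character(pairs2$mate2))

  expect_error(simulateReads(g, SimConfig(genomeLength = 20000L,
                                          coverage = -1, seed = 1L)),
               "coverage")
})

test_that("identical seeds write identical FASTQ files", {
  cfg <- SimConfig(genomeLength = 5000L, seed = 13L)
  g <- generateProgenitorGenome(cfg)
  d1 <- tempfile(); d2 <- tempfile()
  dir.create(d1); dir.create(d2)
  p1 <- writeReadsFastq(simulateReads(g, cfg), file.path(d1, "x"),
                        compress = FALSE)
  p2 <- writeReadsFastq(simulateReads(g, cfg), file.path(d2, "x"),
                        compress = FALSE)
  expect_identical(readLines(p1[1]), readLines(p2[1]))
  expect_identical(readLines(p1[2]), readLines(p2[2]))
  # 4 FASTQ lines per read
  expect_identical(length(readLines(p1[1])), 4L * 500L)
})
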