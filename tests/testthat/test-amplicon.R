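makeAmplicon <- function(len = 260, seed = 1) {
  set.seed(seed)
  ref <- randomDNA(len)
  # place a protospacer at 121..140 with a forced NGG PAM at 141..143
  ref <- paste0(substr(ref, 1, 140), "TGG", substr(ref, 144, len))
  site <- TargetSite("amp", 121L, 140L, "+", "TGG")
  list(ref = ref, site = site)
}

test_that("identical sequences align as one match operation", {
  set.seed(20)
  s <- randomDNA(60)
  aln <- globalAlign(s, s)
  ops <- alignmentOps(aln)
  expect_identical(nrow(ops), 1L)
  expect_identical(ops$op, "match")
  expect_identical(score(aln), 120)
})

test_that("clean deletions and insertions come back as single operations", {
  set.seed(21)
  ref <- randomDNA(120)
  qry <- paste0(substr(ref, 1, 50), substr(ref, 64, 120))   # 13 bp removed
  aln <- globalAlign(ref, qry)
  ops <- alignmentOps(aln)
  dels <- ops[ops$op == "deletion", ]
  expect_identical(nrow(dels), 1L)
  expect_identical(dels$length, 13L)
  expect_identical(nrow(ops[ops$op == "insertion", ]), 0L)

  qry2 <- paste0(substr(ref, 1, 50), "A", substr(ref, 51, 120))
  ops2 <- alignmentOps(globalAlign(ref, qry2))
  inss <- ops2[ops2$op == "insertion", ]
  expect_identical(nrow(inss), 1L)
  expect_identical(inss$length, 1L)

  expect_error(globalAlign("", "ACGT"), "empty")
})

test_that("gapped alignment round-trips the input sequences", {
  set.seed(22)
  for (i in 1:20) {
    ref <- randomDNA(sample(20:40, 1))
    qry <- randomDNA(sample(20:40, 1))
    aln <- globalAlign(ref, qry)
    expect_identical(gsub("-", "", aln@alignedRef), ref)
    expect_identical(gsub("-", "", aln@alignedQuery), qry)
  }
})

test_that("alignment scores match a full-matrix reference on short sequences", {
  set.seed(23)
  for (i in 1:30) {
    ref <- randomDNA(sample(8:30, 1))
    qry <- if (runif(1) < 0.5) {
      randomDNA(sample(8:30, 1))
    } else {
      # a mutated copy: substitution plus a small indel
      x <- strsplit(ref, "")[[1]]
      x[sample(length(x), 1)] <- sample(c("A", "C", "G", "T"), 1)
      drop <- sample(length(x), min(3, length(x) - 2))
      paste(x[-drop], collapse = "")
    }
    aln <- globalAlign(ref, qry)
    expect_equal(score(aln), alignScoreOracle(ref, qry))
  }
})

test_that("indels in repeats are left-aligned", {
  aln <- globalAlign("TTAAAACGTTT", "TTAAACGTTT")
  ops <- alignmentOps(aln)
  del <- ops[ops$op == "deletion", ]
  expect_identical(del$refStart, 3L)
  expect_identical(del$length, 1L)

  aln2 <- globalAlign("TTAAACGTTT", "TTAAAACGTTT")
  ins <- alignmentOps(aln2)[alignmentOps(aln2)$op == "insertion", ]
  expect_identical(ins$refStart, 2L)
})

test_that("target-site mutations are recovered with size and offset", {
  amp <- makeAmplicon()
  cut <- amp$site@start + 16L   # 137

  del13 <- paste0(substr(amp$ref, 1, cut - 7L),
                  substr(amp$ref, cut + 7L, nchar(amp$ref)))
  call <- callTargetMutation(globalAlign(amp$ref, del13), amp$site)
  expect_identical(call@kind, "deletion")
  expect_identical(call@size, 13L)
  expect_true(call@withinTarget)

  none <- callTargetMutation(globalAlign(amp$ref, amp$ref), amp$site)
  expect_identical(none@kind, "none")
  expect_false(none@withinTarget)

  # a 2-bp deletion 50 bp upstream of the window is not a target call
  far <- paste0(substr(amp$ref, 1, 60), substr(amp$ref, 63, nchar(amp$ref)))
  offcall <- callTargetMutation(globalAlign(amp$ref, far), amp$site)
  expect_identical(offcall@kind, "none")
  expect_identical(nrow(offcall@otherVariants), 1L)
  expect_identical(offcall@otherVariants$op, "deletion")

  short <- globalAlign(substr(amp$ref, 1, 100), substr(amp$ref, 1, 100))
  expect_error(callTargetMutation(short, amp$site), "span")
})

test_that("simulated indels of sizes 1-20 are recovered exactly", {
  amp <- makeAmplicon(seed = 3)
  cut <- cutSite <- amp$site@start + 16L
  set.seed(30)
  ok <- 0L
  for (i in 1:50) {
    sz <- sample(1:20, 1)
    if (runif(1) < 0.5) {
      qry <- paste0(substr(amp$ref, 1, cut - ceiling(sz / 2)),
                    substr(amp$ref, cut - ceiling(sz / 2) + sz + 1,
                           nchar(amp$ref)))
      kind <- "deletion"
    } else {
      qry <- paste0(substr(amp$ref, 1, cut), randomDNA(sz),
                    substr(amp$ref, cut + 1, nchar(amp$ref)))
      kind <- "insertion"
    }
    call <- callTargetMutation(globalAlign(amp$ref, qry), amp$site)
    if (call@kind == kind && call@size == sz && call@withinTarget)
      ok <- ok + 1L
  }
  expect_identical(ok, 50L)
})

test_that("nucleus origin follows the catalogued SNV alleles", {
  set.seed(31)
  donorSeq <- randomDNA(200)
  pos <- c(40L, 90L, 150L)
  d <- strsplit(donorSeq, "")[[1]]
  recAllele <- vapply(d[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "", USE.NAMES = FALSE)
  r <- d; r[pos] <- recAllele
  recipSeq <- paste(r, collapse = "")
  snvs <- data.frame(pos = pos, donor = d[pos], recipient = recAllele)

  refForAln <- donorSeq
  expect_identical(
    assignNucleusOrigin(globalAlign(refForAln, recipSeq), snvs)$origin,
    "recipient")
  expect_identical(
    assignNucleusOrigin(globalAlign(refForAln, donorSeq), snvs)$origin,
    "donor")

  mixed <- r; mixed[40L] <- d[40L]
  expect_identical(
    assignNucleusOrigin(globalAlign(refForAln, paste(mixed, collapse = "")),
                        snvs)$origin,
    "ambiguous")

  # a site removed by a deletion is excluded from the vote
  delQ <- paste0(substr(recipSeq, 1, 35), substr(recipSeq, 46, 200))
  res <- assignNucleusOrigin(globalAlign(refForAln, delQ), snvs)
  expect_identical(res$origin, "recipient")
  expect_identical(res$calls$call[res$calls$pos == 40L], "excluded")

  expect_error(
    assignNucleusOrigin(globalAlign(substr(refForAln, 1, 30),
                                    substr(recipSeq, 1, 30)), snvs),
    "covered")

  third <- vapply(seq_along(pos), function(i)
    setdiff(c("A", "C", "G", "T"), c(d[pos[i]], recAllele[i]))[1], "")
  u <- d; u[pos] <- third
  expect_identical(
    assignNucleusOrigin(globalAlign(refForAln, paste(u, collapse = "")),
                        snvs)$origin,
    "uninformative")
})

test_that("in-silico PCR reproduces presence/absence genotyping", {
  set.seed(32)
  tmpl <- randomDNA(1200)
  fwd <- substr(tmpl, 101, 120)
  rev <- revcompChar(substr(tmpl, 881, 900))
  pp <- PrimerPair(fwd, rev, maxProduct = 2000L)

  prod <- insilicoPcr(tmpl, pp)
  expect_identical(nrow(prod), 1L)
  expect_identical(prod$length, 800L)
  expect_identical(prod$product, substr(tmpl, 101, 900))

  # a large deletion removing the reverse site abolishes the product
  cutout <- paste0(substr(tmpl, 1, 600), substr(tmpl, 1001, 1200))
  expect_identical(nrow(insilicoPcr(cutout, pp)), 0L)

  # a control pair on an unrelated region still amplifies
  ctrl <- PrimerPair(substr(tmpl, 21, 40), revcompChar(substr(tmpl, 81, 100)),
                     maxProduct = 500L)
  expect_identical(nrow(insilicoPcr(cutout, ctrl)), 1L)

  # product longer than maxProduct is rejected
  tight <- PrimerPair(fwd, rev, maxProduct = 500L)
  expect_identical(nrow(insilicoPcr(tmpl, tight)), 0L)

  # duplicated reverse site yields a multi-product warning
  dup <- paste0(tmpl, substr(tmpl, 850, 950))
  expect_warning(insilicoPcr(dup, pp), "multiple")

  expect_error(PrimerPair("ACGTACGT", rev), "15")
})
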