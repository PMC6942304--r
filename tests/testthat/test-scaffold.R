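alnRow <- function(contig_id, s_start, s_end, matched = s_end - s_start + 1,
                   strand = "+", q_start = 1, q_end = matched, ident = 1) {
  data.frame(contig_id = contig_id, ref_id = "ref", q_start = q_start,
             q_end = q_end, s_start = s_start, s_end = s_end, strand = strand,
             matched_bases = matched, identity_proxy = ident, n_anchors = 1L,
             tied = FALSE, stringsAsFactors = FALSE)
}

test_that("reference selection maximises coverage, then fewest contigs, then id", {
  a6 <- rbind(do.call(rbind, lapply(1:5, function(i)
    alnRow(paste0("c", i), (i - 1) * 5000 + 1, (i - 1) * 5000 + 4000))),
    alnRow("c6", 25001, 30000))
  a4 <- do.call(rbind, lapply(1:4, function(i)
    alnRow(paste0("c", i), (i - 1) * 7000 + 1, (i - 1) * 7000 + 6250)))
  covered <- function(a) sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(a$s_start, a$s_end))))
  expect_identical(covered(a6), covered(a4))  # both cover 25000 bases
  choice <- selectReference(list(refA = a6, refB = a4))
  expect_identical(choice$ref_id, "refB")  # fewer contigs wins the tie

  big <- rbind(a6, alnRow("c7", 4001, 5000))  # covers 26000 by 7 contigs
  expect_identical(selectReference(list(refA = big, refB = a4))$ref_id, "refA")
  expect_identical(selectReference(list(only = a4))$ref_id, "only")
  expect_error(selectReference(list()), "no reference")
  # permutation invariance, lexicographic final tie-break
  expect_identical(selectReference(list(zeta = a4, alpha = a4))$ref_id, "alpha")
  expect_identical(selectReference(list(alpha = a4, zeta = a4))$ref_id, "alpha")
})

test_that("single full-length contig scaffolds to itself", {
  set.seed(401)
  g <- randomDNA(3000)
  contigs <- Biostrings::DNAStringSet(g)
  names(contigs) <- "c1"
  d <- scaffoldContigs(contigs, alnRow("c1", 1, 3000, 3000), 3000)
  expect_identical(as.character(draftSeq(d)), g)
  expect_identical(nrow(draftJunctions(d)), 0L)
})

test_that("subject gaps become N runs of the gap size under n-fill", {
  set.seed(402)
  g <- randomDNA(1000)
  contigs <- Biostrings::DNAStringSet(c(substr(g, 1, 400),
                                        substr(g, 501, 1000)))
  names(contigs) <- c("a", "b")
  aln <- rbind(alnRow("a", 1, 400, 400), alnRow("b", 501, 1000, 500))
  d <- scaffoldContigs(contigs, aln, 1000)
  expect_identical(length(draftSeq(d)), 1000L)
  j <- draftJunctions(d)
  expect_identical(j$kind, "gap-N")
  expect_identical(j$size, 100L)
  expect_identical(as.character(subseq(draftSeq(d), 401, 500)),
                   strrep("N", 100))

  direct <- scaffoldContigs(contigs, aln, 1000, gapPolicy = "direct")
  expect_identical(length(draftSeq(direct)), 900L)
  expect_identical(draftJunctions(direct)$kind, "direct")
})

test_that("contained contigs are dropped with a warning", {
  set.seed(403)
  g <- randomDNA(1000)
  contigs <- Biostrings::DNAStringSet(c(g, substr(g, 301, 500)))
  names(contigs) <- c("big", "small")
  aln <- rbind(alnRow("big", 1, 1000, 1000), alnRow("small", 301, 500, 200))
  expect_warning(d <- scaffoldContigs(contigs, aln, 1000), "contained")
  expect_identical(as.character(draftSeq(d)), g)
})

test_that("fragmentation round trip reconstructs the genome byte-for-byte", {
  t <- simulatePlastome(SimConfig(), seed = 404)
  ref <- Biostrings::DNAStringSet(as.character(truthSeq(t)))
  names(ref) <- "truth"
  for (s in 1:3) {
    contigs <- fragmentContigs(t, 7, flipProb = 0.5, lossProb = 0, seed = s)
    aln <- suppressWarnings(alignContigs(contigs, ref))
    d <- scaffoldContigs(contigs, aln, length(truthSeq(t)))
    expect_identical(as.character(draftSeq(d)), as.character(truthSeq(t)))
    # draft length conservation invariant
    seg <- draftSegments(d)
    gaps <- draftJunctions(d)
    expect_identical(sum(seg$d_end - seg$d_start + 1L) +
                       sum(gaps$size[gaps$kind == "gap-N"]),
                     length(draftSeq(d)))
  }
})

test_that("lost fragments leave N gaps where the reference says they should", {
  t <- simulatePlastome(SimConfig(), seed = 405)
  ref <- Biostrings::DNAStringSet(as.character(truthSeq(t)))
  names(ref) <- "truth"
  contigs <- fragmentContigs(t, 9, flipProb = 0.3, lossProb = 0.3, seed = 406)
  aln <- suppressWarnings(alignContigs(contigs, ref))
  d <- scaffoldContigs(contigs, aln, length(truthSeq(t)))
  ds <- as.character(draftSeq(d))
  # every non-N draft base matches the genome when aligned back
  expect_true(grepl("N", ds, fixed = TRUE) ||
                sum(Biostrings::width(contigs)) == length(truthSeq(t)))
})

test_that("the parameter sweep stops on acceptance and falls back otherwise", {
  set.seed(407)
  t <- simulatePlastome(SimConfig(genomeLength = 12000, irLength = 1200,
                                  sscLength = 3200), seed = 408)
  cfg <- SimConfig(genomeLength = 12000, irLength = 1200, sscLength = 3200,
                   perBaseError = 0, cpFraction = 1, depth = 40)
  sim <- simulateReads(t, cfg, seed = 409)
  reads <- list(r1 = sim$r1, r2 = sim$r2)
  db <- Biostrings::DNAStringSet(as.character(truthSeq(t)))
  names(db) <- "ref1"

  good <- stubAssembler(t, nBreaks = 3, flipProb = 0)
  res <- runParameterSweep(reads, good, SweepPlan(), db)
  expect_identical(res$mode, "de-novo")
  expect_identical(res$round, 1L)
  expect_identical(nrow(res$provenance), 1L)

  tiny <- function(reads, k, cov)
    Biostrings::DNAStringSet(substr(as.character(truthSeq(t)), 1, 500))
  res2 <- runParameterSweep(reads, tiny, SweepPlan(), db)
  expect_identical(res2$mode, "reference-guided")
  expect_identical(nrow(res2$provenance), 4L)
  expect_false(any(res2$provenance$accepted))
  expect_identical(sum(Biostrings::width(res2$contigs)), 500L)

  lateBloom <- function(reads, k, cov) {
    if (k < 91) stop("assembler crashed")
    fragmentContigs(t, 2, 0, 0, seed = k)
  }
  res3 <- runParameterSweep(reads, lateBloom, SweepPlan(), db)
  expect_identical(res3$mode, "de-novo")
  expect_identical(res3$round, 3L)
  expect_identical(res3$provenance$failed, c(TRUE, TRUE, FALSE))
  expect_identical(res3$provenance$accepted, c(FALSE, FALSE, TRUE))
})
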