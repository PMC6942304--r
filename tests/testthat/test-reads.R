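mkReads <- function(seqs, q = 35L) {
  quals <- vapply(nchar(seqs), function(w)
    strrep(rawToChar(as.raw(q + 33L)), w), character(1))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
  names(x) <- sprintf("r%03d/1", seq_along(seqs))
  x
}

test_that("adapter trimming removes the stated occurrences", {
  adapter <- "AGATCGGA"
  full <- trimAdapters(Biostrings::DNAStringSet(paste0("ACGTACGT", adapter)),
                       adapter)
  expect_identical(as.character(full[[1]]), "ACGTACGT")
  clean <- Biostrings::DNAStringSet("TTTGCACGTGCAT")
  expect_identical(as.character(trimAdapters(clean, adapter)[[1]]),
                   "TTTGCACGTGCAT")
  # a 4-base adapter prefix at the read end is removed at minOverlap = 3
  partial <- Biostrings::DNAStringSet(paste0("CCCTTGCACC", "AGAT"))
  expect_identical(as.character(trimAdapters(partial, adapter)[[1]]),
                   "CCCTTGCACC")
  # read that is pure adapter is dropped
  gone <- trimAdapters(Biostrings::DNAStringSet(adapter), adapter)
  expect_length(gone, 0L)
})

test_that("adapter trimming matches a brute-force placement scan", {
  set.seed(301)
  adapter <- "AGATCGGAAGAGC"
  for (i in 1:40) {
    r <- randomDNA(sample(20:80, 1))
    if (i %% 2 == 0) {  # append a (possibly mutated) adapter prefix
      piece <- substr(adapter, 1, sample(3:nchar(adapter), 1))
      if (i %% 4 == 0) {
        p <- sample(nchar(piece), 1)
        substr(piece, p, p) <- sample(ACGT, 1)
      }
      r <- paste0(r, piece)
    }
    got <- trimAdapters(Biostrings::DNAStringSet(r), adapter)
    want <- bruteTrim(r, adapter)
    if (nchar(want) == 0) expect_length(got, 0L)
    else expect_identical(as.character(got[[1]]), want)
  }
})

test_that("qualities are trimmed in lockstep with sequences", {
  adapter <- "AGATCGGA"
  x <- mkReads(paste0("ACGTACGTAC", adapter))
  out <- trimAdapters(x, adapter)
  expect_identical(Biostrings::width(Biostrings::quality(out)),
                   Biostrings::width(out))
  expect_identical(Biostrings::width(out), 10L)
})

test_that("pair merging reconstructs short fragments and respects quality", {
  set.seed(302)
  frag <- randomDNA(200)
  r1 <- mkReads(substr(frag, 1, 125))
  r2 <- mkReads(rcChar(substr(frag, 76, 200)))
  m <- mergePairs(r1, r2)
  expect_length(m$merged, 1L)
  expect_identical(as.character(m$merged[[1]]), frag)

  # non-overlapping 400 bp fragment stays unmerged
  frag2 <- randomDNA(400)
  n1 <- mkReads(substr(frag2, 1, 125))
  n2 <- mkReads(rcChar(substr(frag2, 276, 400)))
  m2 <- mergePairs(n1, n2)
  expect_length(m2$merged, 0L)
  expect_length(m2$unmergedR1, 1L)

  # disagreeing overlap bases resolve to the higher-quality call
  a <- randomDNA(150)
  r1s <- substr(a, 1, 100)            # covers 1..100
  r2region <- substr(a, 51, 150)      # covers 51..150, overlap 50
  mut <- r2region
  substr(mut, 10, 10) <- setdiff(ACGT, substr(mut, 10, 10))[1]  # pos 60
  substr(mut, 20, 20) <- setdiff(ACGT, substr(mut, 20, 20))[1]  # pos 70
  hi <- mkReads(r1s, q = 40L)
  lo <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(rcChar(mut)),
    Biostrings::PhredQuality(strrep(rawToChar(as.raw(2L + 33L)), 100)))
  names(lo) <- names(hi)
  m3 <- mergePairs(hi, lo)
  expect_length(m3$merged, 1L)
  merged <- as.character(m3$merged[[1]])
  expect_identical(substr(merged, 60, 60), substr(a, 60, 60))  # q40 wins
  expect_identical(substr(merged, 70, 70), substr(a, 70, 70))
})

test_that("digital normalization keeps, discards and downsamples correctly", {
  set.seed(303)
  t <- simulatePlastome(SimConfig(genomeLength = 12000, irLength = 1200,
                                  sscLength = 3200), seed = 304)
  cfg <- SimConfig(genomeLength = 12000, irLength = 1200, sscLength = 3200,
                   perBaseError = 0, cpFraction = 1, depth = 50)
  sim <- simulateReads(t, cfg, seed = 305)
  norm <- normalizeKmerDepth(sim$r1, sim$r2, k = 31, low = 10, high = 500,
                             target = 100, seed = 306)
  # ~50x medians sit between low and target: everything retained, unmodified
  expect_true(all(norm$kept))
  expect_identical(as.character(norm$r1), as.character(sim$r1))

  # singleton k-mers (unrelated random reads) all fall below low
  junk1 <- Biostrings::DNAStringSet(vapply(1:50, function(i) randomDNA(100),
                                           character(1)))
  junk2 <- Biostrings::DNAStringSet(vapply(1:50, function(i) randomDNA(100),
                                           character(1)))
  nj <- normalizeKmerDepth(junk1, junk2, low = 10)
  expect_false(any(nj$kept))

  # output is always a subset of the input
  expect_true(all(as.character(norm$r1) %in% as.character(sim$r1)))
})

test_that("deep input is downsampled towards the target", {
  set.seed(307)
  t <- simulatePlastome(SimConfig(genomeLength = 12000, irLength = 1200,
                                  sscLength = 3200), seed = 308)
  cfg <- SimConfig(genomeLength = 12000, irLength = 1200, sscLength = 3200,
                   perBaseError = 0, cpFraction = 1, depth = 600)
  sim <- simulateReads(t, cfg, seed = 309)
  norm <- normalizeKmerDepth(sim$r1, sim$r2, k = 31, low = 10, high = 1e6,
                             target = 100, seed = 310)
  expected <- sum(pmin(1, 100 / norm$medians))
  expect_gt(sum(norm$kept), 0.8 * expected)
  expect_lt(sum(norm$kept), 1.2 * expected)
})

test_that("depth estimation is read-order invariant and null-safe", {
  set.seed(311)
  g <- randomDNA(2000)
  reads <- vapply(1:100, function(i) {
    p <- sample(1900, 1); substr(g, p, p + 99)
  }, character(1))
  d1 <- estimateDepth(reads, g)
  d2 <- estimateDepth(rev(reads), g)
  expect_identical(d1$depth, d2$depth)
  z <- estimateDepth(character(0), g)
  expect_identical(z$median, 0)
  expect_true(all(z$depth == 0L))
  expect_error(estimateDepth(reads, substr(g, 1, 10)), "shorter than k")
})

test_that("k-mer spectrum counts canonical k-mers", {
  sp <- kmerSpectrum(c("ACGTA", "TACGT"), k = 5)
  # ACGTA is the canonical form of both reads' single 5-mer
  expect_identical(nrow(sp), 1L)
  expect_identical(sp$kmer, "ACGTA")
  expect_identical(sp$count, 2L)
  expect_error(kmerSpectrum("ACGT", k = 4), "odd")
})
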