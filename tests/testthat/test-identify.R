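test_that("ACS distance: identity, symmetry, divergence monotonicity", {
  set.seed(601)
  a <- randomDNA(2000, 0.4)
  expect_equal(acsDistance(a, a), 0, tolerance = 1e-12)
  b <- randomDNA(1500, 0.4)
  expect_equal(acsDistance(a, b), acsDistance(b, a), tolerance = 1e-12)
  expect_error(acsDistance("ACGT", a), ">= 10")

  t <- simulatePlastome(SimConfig(genomeLength = 12000, irLength = 1200,
                                  sscLength = 3200), seed = 602)
  d <- vapply(c(0.01, 0.05, 0.10), function(div)
    acsDistance(truthSeq(t), truthSeq(evolveGenome(t, div, seed = 603))),
    numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("matching statistics under ACS equal the brute-force oracle", {
  set.seed(604)
  a <- randomDNA(300); b <- randomDNA(400)
  expect_identical(matchingStatistics(a, b, TRUE), bruteMS(a, b, TRUE))
})

test_that("database ranking is exact for verbatim queries and deterministic", {
  set.seed(605)
  db <- Biostrings::DNAStringSet(vapply(1:6, function(i) randomDNA(1000),
                                        character(1)))
  names(db) <- sprintf("S%03d", 1:6)
  tax <- data.frame(sample_id = names(db),
                    genus = rep(c("GA", "GB"), each = 3),
                    species = paste0("sp", 1:6))
  r <- rankDatabase(db[[4]], db, tax)
  h <- hits(r)
  expect_identical(h$subject_id[1], "S004")
  expect_equal(h$distance[1], 0, tolerance = 1e-12)
  expect_identical(h$rank, 1:6)
  expect_false(is.unsorted(h$distance))

  one <- rankDatabase(db[[1]], db[1], tax)
  expect_identical(nrow(hits(one)), 1L)
  expect_error(rankDatabase(db[[1]], db[0]), "empty")
})

test_that("simulated PCR recovers planted markers exactly once", {
  t <- simulatePlastome(SimConfig(), seed = 606)
  primers <- defaultPrimers()
  g <- as.character(truthSeq(t))
  m <- truthMarkers(t)
  for (mk in c("rbcL", "matK", "rdna")) {
    amp <- insilicoPcr(g, primers[primers$marker == mk, ])
    expect_identical(nrow(amp), 1L)
    expect_identical(amp$start, GenomicRanges::start(m[mk]))
    expect_identical(amp$end, GenomicRanges::end(m[mk]))
    expect_identical(amp$strand, as.character(GenomicRanges::strand(m[mk])))
    expect_identical(amp$sequence, as.character(markerSequence(t, mk)))
  }
})

test_that("PCR honours the mismatch budget and the 3' anchor", {
  set.seed(607)
  primer <- data.frame(name = "p", marker = "x",
                       forward = "ACGGATTCAGGATCACGTTG",
                       reverse = "TTGACCGTAGGCATTAGCAC",
                       product_min = 80, product_max = 200)
  core <- randomDNA(80)
  templ <- paste0(randomDNA(50), primer$forward, core,
                  rcChar(primer$reverse), randomDNA(50))
  expect_identical(nrow(insilicoPcr(templ, primer)), 1L)

  # one internal mismatch in the forward site: still amplifies
  mut <- templ
  substr(mut, 55, 55) <- setdiff(ACGT, substr(mut, 55, 55))[1]
  expect_identical(nrow(insilicoPcr(mut, primer)), 1L)
  expect_identical(insilicoPcr(mut, primer)$fwd_mismatches, 1L)

  # three internal mismatches exceed the budget
  mut3 <- templ
  for (p in c(53, 57, 61))
    substr(mut3, p, p) <- setdiff(ACGT, substr(mut3, p, p))[1]
  expect_identical(nrow(insilicoPcr(mut3, primer)), 0L)

  # a single mismatch at the primer 3' terminus kills the site
  anchor <- templ
  substr(anchor, 70, 70) <- setdiff(ACGT, substr(anchor, 70, 70))[1]
  expect_identical(nrow(insilicoPcr(anchor, primer)), 0L)

  # N-masked binding site never amplifies
  nn <- templ
  substr(nn, 51, 70) <- strrep("N", 20)
  expect_identical(nrow(insilicoPcr(nn, primer)), 0L)

  # random templates essentially never amplify at zero mismatches
  expect_identical(nrow(insilicoPcr(randomDNA(10000), primer,
                                    maxMismatch = 0)), 0L)
})

test_that("PCR is strand-symmetric", {
  set.seed(608)
  primer <- defaultPrimers()[1, ]
  t <- simulatePlastome(SimConfig(), seed = 609)
  g <- as.character(truthSeq(t))
  fwd <- insilicoPcr(g, primer)
  rev <- insilicoPcr(rcChar(g), primer)
  expect_identical(nrow(fwd), nrow(rev))
  expect_identical(fwd$sequence, rev$sequence)
  expect_identical(fwd$start, nchar(g) - rev$end + 1L)
  expect_true(all(fwd$strand != rev$strand))
})

test_that("barcode extraction tries pairs in table order and reports misses", {
  t <- simulatePlastome(SimConfig(), seed = 610)
  bc <- extractBarcode(truthSeq(t), "rbcL")
  expect_identical(as.character(bc), as.character(markerSequence(t, "rbcL")))
  expect_identical(attr(bc, "primer_name"), "rbcL_syn_F1R1")

  # first listed pair wins when two amplify
  tab <- rbind(defaultPrimers()[1, ], defaultPrimers()[1, ])
  tab$name <- c("first", "second")
  bc2 <- extractBarcode(truthSeq(t), "rbcL", primerTable = tab)
  expect_identical(attr(bc2, "primer_name"), "first")

  # marker region replaced by Ns -> no barcode
  g <- as.character(truthSeq(t))
  m <- truthMarkers(t)["rbcL"]
  substr(g, GenomicRanges::start(m), GenomicRanges::end(m)) <-
    strrep("N", width(m))
  expect_null(extractBarcode(g, "rbcL"))
  expect_error(extractBarcode(g, "nope"), "unknown marker")
})

test_that("verbatim queries identify perfectly", {
  set.seed(611)
  db <- Biostrings::DNAStringSet(vapply(1:8, function(i) randomDNA(800),
                                        character(1)))
  names(db) <- sprintf("S%03d", 1:8)
  tax <- data.frame(sample_id = names(db),
                    genus = rep(c("GA", "GB"), each = 4),
                    species = paste0("sp", 1:8))
  ev <- evaluateIdentification(db[c(2, 5, 7)], tax$genus[c(2, 5, 7)],
                               tax$species[c(2, 5, 7)], db, tax)
  expect_identical(ev$genus_agreement, 1)
  expect_identical(ev$species_agreement, 1)
  expect_identical(nrow(ev$table), 3L)
})
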