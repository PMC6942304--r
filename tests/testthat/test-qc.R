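test_that("assembly error is the absolute natural-log length ratio", {
  expect_identical(assemblyError(150000, 150000), 0)
  expect_equal(assemblyError(165000, 150000), abs(log(1.1)), tolerance = 1e-12)
  expect_equal(assemblyError(135000, 150000), abs(log(0.9)), tolerance = 1e-12)
  # missing sequence counts more than the same proportion of extra sequence
  expect_gt(assemblyError(135000, 150000), assemblyError(165000, 150000))
  # ratio invariance
  set.seed(501)
  for (i in 1:20) {
    a <- runif(1, 1e3, 2e5); b <- runif(1, 1e3, 2e5); k <- runif(1, 0.1, 50)
    expect_equal(assemblyError(k * a, k * b), assemblyError(a, b),
                 tolerance = 1e-12)
  }
  expect_error(assemblyError(0, 100), "positive")
  expect_error(assemblyError(100, -1), "positive")
})

test_that("classification boundary is inclusive at the threshold", {
  expect_identical(classifyAssembly(assemblyError(165000, 150000)), "good")
  expect_identical(classifyAssembly(assemblyError(135000, 150000)), "poor")
  expect_identical(classifyAssembly(0.1), "poor")
  expect_identical(classifyAssembly(0.1 - 1e-12), "good")
  expect_error(classifyAssembly(-0.1), ">= 0")
})

test_that("GC content weights ambiguity codes by expected GC", {
  expect_identical(gcContent("ATGC"), 0.5)
  expect_identical(gcContent("AAAA"), 0)
  expect_identical(gcContent("GGCC"), 1)
  expect_identical(gcContent("SSWW"), 0.5)
  expect_identical(gcContent("RYKMN"), 0.5)
  expect_equal(gcContent("BVDH"), 0.5, tolerance = 1e-12)
  expect_error(gcContent(""), "non-empty")
})

test_that("maximal repeat enumeration matches the brute-force oracle", {
  set.seed(502)
  for (i in 1:40) {
    s <- randomDNA(sample(30:250, 1), gc = sample(c(0.25, 0.5), 1))
    if (i %% 3 == 0) {  # plant a direct or inverted copy
      piece <- substr(s, 5, 5 + sample(10:25, 1))
      ins <- if (i %% 2 == 0) piece else rcChar(piece)
      s <- paste0(s, randomDNA(10), ins, randomDNA(5))
    }
    minLen <- sample(4:10, 1)
    got <- findMaximalRepeats(s, minLen)
    want <- bruteMaxRepeats(s, minLen)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("maximal repeat example and null case", {
  r <- findMaximalRepeats("ATCGATCGTT", minLen = 4)
  direct <- r[r$orientation == "direct", ]
  expect_identical(direct$start1, 1L)
  expect_identical(direct$start2, 5L)
  expect_identical(direct$length, 4L)
  set.seed(503)
  expect_identical(nrow(findMaximalRepeats(randomDNA(1000), minLen = 20)), 0L)
})

test_that("inverted repeat detection recovers planted IRs exactly", {
  for (s in 1:3) {
    t <- simulatePlastome(SimConfig(), seed = 510 + s)
    ir <- detectInvertedRepeat(truthSeq(t))
    r <- truthRegions(t)
    expect_identical(start(ir), start(r)[c(2, 4)])
    expect_identical(end(ir), end(r)[c(2, 4)])
  }
  set.seed(504)
  expect_null(detectInvertedRepeat(randomDNA(5000)))
})

test_that("the longest of two inverted candidates wins", {
  set.seed(505)
  a <- randomDNA(1200)
  b <- randomDNA(2000)
  s <- paste0(randomDNA(500), a, randomDNA(500), b, randomDNA(500),
              rcChar(b), randomDNA(500), rcChar(a), randomDNA(500))
  ir <- detectInvertedRepeat(s, minLen = 1000)
  expect_identical(width(ir)[1], 2000L)
})

test_that("repeat content excludes the IR and counts union bases", {
  set.seed(506)
  expect_identical(repeatContent(randomDNA(3000)), 0L)
  t <- simulatePlastome(SimConfig(), seed = 507)
  expect_identical(repeatContent(truthSeq(t)), 0L)  # IR is the only repeat
  # a planted 50 bp direct pair outside the IR counts both copies
  g <- as.character(truthSeq(t))
  piece <- substr(g, 1001, 1050)
  substr(g, 5001, 5050) <- piece
  expect_identical(repeatContent(g), 100L)
  expect_identical(repeatContent(g, sumMode = "pairs"), 100L)
})

test_that("Welch t-test equals the closed form and handles edge cases", {
  set.seed(508)
  for (i in 1:100) {
    x <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:30, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    got <- welchTTest(x, y)
    want <- bruteWelch(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
  x <- c(1, 2, 3, 4)
  same <- welchTTest(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  shifted <- welchTTest(x, x + 10)
  expect_lt(shifted$p, 0.001)
  expect_error(welchTTest(1, c(1, 2)), "n >= 2")
  expect_error(welchTTest(c(1, 1, 1), c(2, 2, 2)), "degenerate")
})

test_that("good/poor screen flags the discriminating parameter", {
  set.seed(509)
  n <- 30
  tab <- data.frame(
    label = rep(c("good", "poor"), each = n),
    fragment_length = c(rnorm(n, 400, 40), rnorm(n, 150, 40)),
    reads = rnorm(2 * n, 5e6, 5e5),
    constant_ish = rep(c(1, 2, 1, 2), length.out = 2 * n))
  res <- compareGoodPoor(tab, c("fragment_length", "reads", "constant_ish"))
  expect_lt(res$p[res$parameter == "fragment_length"], 0.01)
  expect_equal(res$p[res$parameter == "constant_ish"], 1)
  expect_true(all(sign(res$t) == sign(res$mean_good - res$mean_poor)))
  expect_error(compareGoodPoor(tab, "nope"), "nope")
  allGood <- tab; allGood$label <- "good"
  expect_error(compareGoodPoor(allGood, "reads"), "per label")
  withHolm <- compareGoodPoor(tab, c("fragment_length", "reads"), holm = TRUE)
  expect_true(all(withHolm$p_holm >= withHolm$p))
})

test_that("assemblyReport bundles the QC measures", {
  t <- simulatePlastome(SimConfig(), seed = 511)
  db <- buildTaxonomyDb(SimConfig(genomeLength = 12000, irLength = 1200,
                                  sscLength = 3200, nGenera = 2,
                                  speciesPerGenus = 2), seed = 512)
  dbs <- Biostrings::DNAStringSet(c(
    vapply(db$genomes, function(g) as.character(truthSeq(g)), character(1)),
    full = as.character(truthSeq(t))))
  rep <- assemblyReport(truthSeq(t), dbs, sampleId = "t")
  expect_identical(rep@refMatchId, "full")
  expect_identical(rep@label, "good")
  expect_equal(rep@error, 0)
  expect_identical(width(rep@ir)[1], 3000L)
  # an empty assembly is reported as failed
  expect_identical(assemblyReport("", dbs)@label, "failed")
})
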