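#' Idealised stub assembler
#'
#' The pluggable-assembler seam of [runParameterSweep()] expects an external
#' de novo assembler; this stub stands in for one in demonstrations and
#' tests. It "assembles" by fragmenting a known genome into contigs (the
#' k-mer value seeds the fragmentation), which exercises the sweep, alignment
#' and scaffolding stages without shipping an assembler.
#'
#' @param truth the [PlastomeTruth-class] the reads came from
#' @param nBreaks,flipProb fragmentation parameters
#' @return \code{function(reads, k, covCutoff)} returning contigs
#' @export
stubAssembler <- function(truth, nBreaks = 5L, flipProb = 0.5) {
  force(truth)
  function(reads, k, covCutoff) {
    fragmentContigs(truth, nBreaks = nBreaks, flipProb = flipProb,
                    lossProb = 0, seed = as.integer(k))
  }
}

#' End-to-end synthetic demonstration
#'
#' Generates a synthetic world (taxonomy database plus a "known unknown"
#' specimen), simulates herbarium reads, runs the pipeline in order --
#' adapter trimming, k-mer depth normalization, pair merging, the assembly
#' sweep (with the bundled [stubAssembler()]), reference selection and
#' scaffolding, assembly QC, ACS identification and barcode extraction --
#' and writes every artifact plus a JSON provenance file to \code{outDir}.
#' Byte-reproducible under a fixed seed.
#'
#' @param seed RNG seed driving the whole run
#' @param outDir output directory (created if missing)
#' @param config a [SimConfig()]
#' @param quiet suppress progress messages
#' @return list: report ([AssemblyReport-class]), ranking
#'   ([MatchRanking-class]), draft ([Draft-class]), barcodes, sweep
#'   provenance, artifact paths
#' @export
runDemo <- function(seed = 7L, outDir = tempfile("skimplast_demo_"),
                    config = SimConfig(), quiet = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[skimplast] ", ...)
  paths <- list()

  say("simulating taxonomy database and specimen (seed ", seed, ")")
  db <- buildTaxonomyDb(config, seed = seed)
  dbSeqs <- Biostrings::DNAStringSet(vapply(db$genomes, function(g)
    as.character(truthSeq(g)), character(1)))
  qworld <- simulateQueries(db, 1, divergence = config@intraSpeciesDivergence)
  truth <- qworld$truths[[1]]
  truthTax <- qworld$taxonomy[1, ]

  sim <- simulateReads(truth, config, seed = NULL)
  paths$r1 <- file.path(outDir, "reads_R1.fastq")
  paths$r2 <- file.path(outDir, "reads_R2.fastq")
  writeSequences(sim$r1, paths$r1, "fastq")
  writeSequences(sim$r2, paths$r2, "fastq")
  paths$genome <- file.path(outDir, "true_genome.fasta")
  g <- Biostrings::DNAStringSet(as.character(truthSeq(truth)))
  names(g) <- truthTax$sample_id
  writeSequences(g, paths$genome)

  say("trimming, normalizing and merging ", length(sim$r1), " read pairs")
  adapter <- "AGATCGGAAGAGC"
  t1 <- trimAdapters(sim$r1, adapter)
  t2 <- trimAdapters(sim$r2, adapter)
  n <- min(length(t1), length(t2))
  norm <- normalizeKmerDepth(t1[seq_len(n)], t2[seq_len(n)])
  mrg <- mergePairs(norm$r1, norm$r2)
  readPool <- c(.asChar(mrg$merged), .asChar(mrg$unmergedR1),
                .asChar(mrg$unmergedR2))
  say(length(mrg$merged), " pairs merged, ",
      length(mrg$unmergedR1), " left paired")

  say("running assembly parameter sweep")
  sweep <- runParameterSweep(list(r1 = norm$r1, r2 = norm$r2),
                             assembler = stubAssembler(truth),
                             plan = SweepPlan(), referenceDb = dbSeqs)
  contigs <- sweep$contigs
  paths$contigs <- file.path(outDir, "contigs.fasta")
  writeSequences(contigs, paths$contigs)

  say("selecting reference and scaffolding ", length(contigs), " contigs")
  alnByRef <- lapply(seq_along(dbSeqs), function(i)
    suppressWarnings(alignContigs(contigs, dbSeqs[i])))
  names(alnByRef) <- names(dbSeqs)
  choice <- selectReference(alnByRef)
  draft <- scaffoldContigs(contigs, alnByRef[[choice$ref_id]],
                           referenceLength =
                             Biostrings::width(dbSeqs)[
                               match(choice$ref_id, names(dbSeqs))])
  paths$draft <- file.path(outDir, "draft.fasta")
  d <- Biostrings::DNAStringSet(as.character(draftSeq(draft)))
  names(d) <- paste0(truthTax$sample_id, "_draft")
  writeSequences(d, paths$draft)

  say("QC and identification")
  report <- assemblyReport(draftSeq(draft), dbSeqs, taxonomy = db$taxonomy,
                           reads = readPool, sampleId = truthTax$sample_id)
  ranking <- rankDatabase(draftSeq(draft), dbSeqs, taxonomy = db$taxonomy,
                          queryId = truthTax$sample_id)
  barcodes <- list(rbcL = extractBarcode(draftSeq(draft), "rbcL"),
                   matK = extractBarcode(draftSeq(draft), "matK"))
  bseqs <- Filter(Negate(is.null), barcodes)
  if (length(bseqs)) {
    paths$barcodes <- file.path(outDir, "barcodes.fasta")
    bset <- Biostrings::DNAStringSet(vapply(bseqs, as.character, character(1)))
    names(bset) <- names(bseqs)
    writeSequences(bset, paths$barcodes)
  }
  paths$ranking <- file.path(outDir, "ranking.tsv")
  utils::write.table(hits(ranking), paths$ranking, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$provenance <- file.path(outDir, "provenance.json")
  jsonlite::write_json(list(
    seed = seed,
    sample = as.list(truthTax),
    sweep = sweep$provenance,
    mode = sweep$mode,
    reference = choice,
    junctions = draftJunctions(draft),
    report = list(sample_id = report@sampleId,
                  assembly_length = report@assemblyLength,
                  ref_match = report@refMatchId,
                  ref_match_length = report@refMatchLength,
                  error = report@error, label = report@label,
                  gc = report@gc, repeat_content = report@repeatContent,
                  depth_median = report@depthMedian),
    top_hit = as.list(hits(ranking)[1, ])),
    paths$provenance, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (!quiet) { show(report); show(ranking) }
  list(report = report, ranking = ranking, draft = draft, barcodes = barcodes,
       sweep = sweep, truth = truth, truthTaxonomy = truthTax,
       artifacts = paths)
}
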