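#' Simulation configuration
#'
#' Parameters of the synthetic plastome / herbarium read simulator. Defaults
#' describe a desk-scale study: a 30 kb quadripartite genome (3 kb inverted
#' repeats, 3.6 kb small single-copy region), 37% GC, a taxonomically
#' structured database of 5 genera x 4 species, 2 x 125 nt paired-end reads
#' from fragments with a 350 bp median insert, and a plastome read fraction
#' of 0.8 modelling the high-copy plastid share of a genome skim.
#'
#' @slot genomeLength total genome length (bp)
#' @slot irLength length of each inverted repeat copy (bp)
#' @slot sscLength length of the small single-copy region (bp)
#' @slot gc target GC fraction in [0,1]
#' @slot nGenera,speciesPerGenus database shape
#' @slot interGenusDivergence,intraGenusDivergence,intraSpeciesDivergence
#'   expected substitution fractions used when evolving database relatives
#'   and query specimens
#' @slot readLength read length (nt)
#' @slot insertMedian median sequencing insert (bp)
#' @slot fragmentMean,fragmentSd mean and sd (bp) of the log-normal fragment
#'   length distribution modelling herbarium DNA degradation
#' @slot perBaseError per-base sequencing error probability
#' @slot cpFraction probability that a read pair is drawn from the plastome
#'   rather than a random background genome
#' @slot depth target total read depth (x)
#' @slot seed default RNG seed
#' @export
setClass("SimConfig", representation(
  genomeLength = "numeric", irLength = "numeric", sscLength = "numeric",
  gc = "numeric", nGenera = "numeric", speciesPerGenus = "numeric",
  interGenusDivergence = "numeric", intraGenusDivergence = "numeric",
  intraSpeciesDivergence = "numeric", readLength = "numeric",
  insertMedian = "numeric", fragmentMean = "numeric", fragmentSd = "numeric",
  perBaseError = "numeric", cpFraction = "numeric", depth = "numeric",
  seed = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  fr <- c(gc = object@gc, perBaseError = object@perBaseError,
          cpFraction = object@cpFraction,
          interGenusDivergence = object@interGenusDivergence,
          intraGenusDivergence = object@intraGenusDivergence,
          intraSpeciesDivergence = object@intraSpeciesDivergence)
  bad <- names(fr)[fr < 0 | fr > 1]
  if (length(bad)) msg <- c(msg, paste0("fractions outside [0,1]: ",
                                        paste(bad, collapse = ", ")))
  if (2 * object@irLength + object@sscLength >= object@genomeLength)
    msg <- c(msg, "2*irLength + sscLength must be < genomeLength")
  if (object@nGenera < 1 || object@speciesPerGenus < 1)
    msg <- c(msg, "nGenera and speciesPerGenus must be >= 1")
  if (object@depth <= 0) msg <- c(msg, "depth must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#' @param genomeLength,irLength,sscLength,gc,nGenera,speciesPerGenus
#'   see slot documentation
#' @param interGenusDivergence,intraGenusDivergence,intraSpeciesDivergence
#'   substitution fractions
#' @param readLength,insertMedian,fragmentMean,fragmentSd,perBaseError
#'   read simulation parameters
#' @param cpFraction,depth,seed read simulation parameters
#' @return a validated \code{SimConfig} object
#' @export
SimConfig <- function(genomeLength = 30000, irLength = 3000, sscLength = 3600,
                      gc = 0.37, nGenera = 5, speciesPerGenus = 4,
                      interGenusDivergence = 0.05, intraGenusDivergence = 0.02,
                      intraSpeciesDivergence = 0.003, readLength = 125,
                      insertMedian = 350, fragmentMean = 350, fragmentSd = 120,
                      perBaseError = 0.002, cpFraction = 0.8, depth = 50,
                      seed = 1) {
  new("SimConfig", genomeLength = genomeLength, irLength = irLength,
      sscLength = sscLength, gc = gc, nGenera = nGenera,
      speciesPerGenus = speciesPerGenus,
      interGenusDivergence = interGenusDivergence,
      intraGenusDivergence = intraGenusDivergence,
      intraSpeciesDivergence = intraSpeciesDivergence,
      readLength = readLength, insertMedian = insertMedian,
      fragmentMean = fragmentMean, fragmentSd = fragmentSd,
      perBaseError = perBaseError, cpFraction = cpFraction, depth = depth,
      seed = seed)
}

#' Annotated synthetic plastome
#'
#' A simulated quadripartite plastome together with its ground truth: the
#' LSC / IRa / SSC / IRb partition, planted marker loci (rbcL, matK, rdna)
#' with strand, and the taxon it belongs to. Invariants: the four regions
#' partition the genome in order; the IRb sequence is the reverse complement
#' of IRa; markers are disjoint and lie outside the inverted repeats.
#'
#' @slot seq the genome (\code{DNAString})
#' @slot regions \code{IRanges} named LSC, IRa, SSC, IRb
#' @slot markers \code{GRanges} named rbcL, matK, rdna (with strand)
#' @slot taxon named character: genus, species, sample_id
#' @export
setClass("PlastomeTruth", representation(
  seq = "DNAString", regions = "IRanges", markers = "GRanges",
  taxon = "character"
))

setValidity("PlastomeTruth", function(object) {
  msg <- character()
  r <- object@regions
  n <- length(object@seq)
  if (!identical(names(r), c("LSC", "IRa", "SSC", "IRb")))
    return("regions must be named LSC, IRa, SSC, IRb in order")
  if (start(r)[1] != 1 || end(r)[4] != n ||
      any(start(r)[-1] != end(r)[-4] + 1))
    msg <- c(msg, "regions must partition [1, length] in order")
  ira <- subseq(object@seq, start(r)[2], end(r)[2])
  irb <- subseq(object@seq, start(r)[4], end(r)[4])
  if (as.character(irb) != as.character(Biostrings::reverseComplement(ira)))
    msg <- c(msg, "IRb must be the reverse complement of IRa")
  m <- object@markers
  if (length(m)) {
    mr <- IRanges::ranges(m)
    if (!IRanges::isDisjoint(mr)) msg <- c(msg, "markers must be disjoint")
    irs <- r[c("IRa", "IRb")]
    if (any(IRanges::overlapsAny(mr, irs)))
      msg <- c(msg, "markers must lie outside the inverted repeats")
  }
  if (!all(c("genus", "species", "sample_id") %in% names(object@taxon)))
    msg <- c(msg, "taxon must name genus, species, sample_id")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PlastomeTruth", function(object) {
  r <- object@regions
  cat("PlastomeTruth:", object@taxon[["sample_id"]],
      sprintf("(%s / %s)\n", object@taxon[["genus"]], object@taxon[["species"]]))
  cat(sprintf("  genome: %d bp | LSC %d, IRa %d, SSC %d, IRb %d\n",
              length(object@seq), width(r)[1], width(r)[2], width(r)[3],
              width(r)[4]))
  cat("  markers:", paste(sprintf("%s[%d-%d,%s]", names(object@markers),
                                  GenomicRanges::start(object@markers),
                                  GenomicRanges::end(object@markers),
                                  as.character(GenomicRanges::strand(object@markers))),
                          collapse = " "), "\n")
})

#' @describeIn PlastomeTruth-class the genome sequence
#' @param x a \code{PlastomeTruth}
#' @export
truthSeq <- function(x) x@seq

#' @describeIn PlastomeTruth-class the LSC/IRa/SSC/IRb partition
#' @export
truthRegions <- function(x) x@regions

#' @describeIn PlastomeTruth-class planted marker loci
#' @export
truthMarkers <- function(x) x@markers

#' @describeIn PlastomeTruth-class genus/species/sample_id
#' @export
truthTaxon <- function(x) x@taxon

#' Reference-guided draft assembly
#'
#' The product of [scaffoldContigs()]: a single draft sequence, the placed
#' contig segments (contig coordinates, strand, and draft coordinates) and
#' the junctions between them (gap-N, direct, or overlap-merged). Every draft
#' base traces to exactly one contig base or to an N gap.
#'
#' @slot seq draft sequence (\code{DNAString})
#' @slot segments data.frame: contig_id, q_start, q_end, strand, d_start, d_end
#' @slot junctions data.frame: kind, position, size
#' @slot refId id of the guiding reference
#' @export
setClass("Draft", representation(
  seq = "DNAString", segments = "data.frame", junctions = "data.frame",
  refId = "character"
))

setValidity("Draft", function(object) {
  s <- object@segments
  if (nrow(s)) {
    if (is.unsorted(s$d_start)) return("segments must be ordered in draft")
    if (any(s$d_end[-nrow(s)] >= s$d_start[-1]))
      return("segments must not overlap in draft coordinates")
    seg <- sum(s$d_end - s$d_start + 1)
    gaps <- sum(object@junctions$size[object@junctions$kind == "gap-N"])
    if (seg + gaps != length(object@seq))
      return("draft length must equal segment lengths plus N gaps")
  }
  TRUE
})

setMethod("show", "Draft", function(object) {
  cat(sprintf("Draft: %d bp from %d contigs vs reference '%s'\n",
              length(object@seq), nrow(object@segments), object@refId))
  if (nrow(object@junctions)) {
    tab <- table(object@junctions$kind)
    cat("  junctions:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
})

#' @describeIn Draft-class the draft sequence
#' @param x a \code{Draft}
#' @export
draftSeq <- function(x) x@seq

#' @describeIn Draft-class placed contig segments
#' @export
draftSegments <- function(x) x@segments

#' @describeIn Draft-class junction records
#' @export
draftJunctions <- function(x) x@junctions

#' Multi-parameter assembly sweep plan
#'
#' The de novo assembly rounds tried in order: paired k-mer values and low
#' coverage cut-offs (defaults k = 51, 71, 91, 111 with cut-offs 10, 7, 15,
#' 20), plus the acceptance criteria a round must meet (minimum total
#' plastid-matching contig length and minimum median k-mer coverage).
#'
#' @slot kmerValues assembler k-mer sizes, tried in order
#' @slot covCutoffs low coverage cut-offs, paired positionally with kmerValues
#' @slot minTotalLength acceptance: minimum total plastid-matching contig
#'   length (bp); \code{NA} means 0.8 x the median reference length
#' @slot minKmerCoverage acceptance: minimum median pseudo-mapping depth
#' @export
setClass("SweepPlan", representation(
  kmerValues = "integer", covCutoffs = "integer",
  minTotalLength = "numeric", minKmerCoverage = "numeric"
))

setValidity("SweepPlan", function(object) {
  if (length(object@kmerValues) == 0) return("kmerValues must be non-empty")
  if (length(object@kmerValues) != length(object@covCutoffs))
    return("kmerValues and covCutoffs must be paired (equal length)")
  TRUE
})

#' @rdname SweepPlan-class
#' @param kmerValues,covCutoffs,minTotalLength,minKmerCoverage see slots
#' @return a validated \code{SweepPlan}
#' @export
SweepPlan <- function(kmerValues = c(51L, 71L, 91L, 111L),
                      covCutoffs = c(10L, 7L, 15L, 20L),
                      minTotalLength = NA_real_, minKmerCoverage = 10) {
  new("SweepPlan", kmerValues = as.integer(kmerValues),
      covCutoffs = as.integer(covCutoffs),
      minTotalLength = as.numeric(minTotalLength),
      minKmerCoverage = as.numeric(minKmerCoverage))
}

#' Per-sample assembly QC report
#'
#' Bundles the quality measures of one draft assembly: assembly and closest
#' reference match lengths, the length-ratio error |ln(L_asm/L_ref)| with its
#' good/poor label (poor at error >= 0.1), GC content, non-IR repeat content,
#' detected inverted repeat, and median pseudo-mapping depth.
#'
#' @slot sampleId sample identifier
#' @slot assemblyLength,refMatchLength lengths (bp)
#' @slot refMatchId id of the top-ranked database match
#' @slot error |ln(assemblyLength / refMatchLength)|
#' @slot label "good", "poor" or "failed"
#' @slot gc GC fraction
#' @slot repeatContent summed non-IR repeat bases
#' @slot ir detected inverted repeat (\code{IRanges} of length 2, or empty)
#' @slot depthMedian median pseudo-mapping depth (NA if no reads supplied)
#' @export
setClass("AssemblyReport", representation(
  sampleId = "character", assemblyLength = "numeric",
  refMatchLength = "numeric", refMatchId = "character", error = "numeric",
  label = "character", gc = "numeric", repeatContent = "numeric",
  ir = "IRanges", depthMedian = "numeric"
))

setValidity("AssemblyReport", function(object) {
  msg <- character()
  if (!object@label %in% c("good", "poor", "failed"))
    msg <- c(msg, "label must be good, poor or failed")
  if (!is.na(object@error) && object@error < 0)
    msg <- c(msg, "error must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AssemblyReport", function(object) {
  cat(sprintf("AssemblyReport: %s [%s]\n", object@sampleId, object@label))
  cat(sprintf("  assembly %d bp vs match '%s' (%d bp): error %.5f\n",
              as.integer(object@assemblyLength), object@refMatchId,
              as.integer(object@refMatchLength), object@error))
  cat(sprintf("  GC %.3f | non-IR repeats %d bp | IR %s | median depth %s\n",
              object@gc, as.integer(object@repeatContent),
              if (length(object@ir)) sprintf("%d bp", width(object@ir)[1]) else "none",
              if (is.na(object@depthMedian)) "NA" else
                sprintf("%.0fx", object@depthMedian)))
})

#' Ranked database hits for one query
#'
#' Ordered average-common-substring hits of a query against a reference
#' database, with taxonomy labels. Hits are sorted by ascending distance,
#' ties broken by subject id.
#'
#' @slot queryId query identifier
#' @slot marker marker class of the query (cpDNA, rDNA, matK, rbcL)
#' @slot hits data.frame: subject_id, genus, species, distance, rank
#' @export
setClass("MatchRanking", representation(
  queryId = "character", marker = "character", hits = "data.frame"
))

setValidity("MatchRanking", function(object) {
  h <- object@hits
  if (is.unsorted(h$distance)) return("hits must be sorted by distance")
  TRUE
})

setMethod("show", "MatchRanking", function(object) {
  cat(sprintf("MatchRanking: query '%s' (%s), %d hits\n", object@queryId,
              object@marker, nrow(object@hits)))
  print(utils::head(object@hits, 3))
})

#' @describeIn MatchRanking-class the ranked hit table
#' @param x a \code{MatchRanking}
#' @export
hits <- function(x) x@hits
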