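BASES <- c("A", "C", "G", "T")

.randomDNA <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Deterministically replace degenerate primer codes by one concrete base so
# planted primer sites are plain DNA (the primer still binds by set
# intersection).
.concretizeIupac <- function(s) {
  first <- c(R = "A", Y = "C", S = "C", W = "A", K = "G", M = "A",
             B = "C", D = "A", H = "A", V = "A", N = "A")
  chartr(paste(names(first), collapse = ""), paste(first, collapse = ""),
         toupper(s))
}

.comp1 <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]

#' Synthetic primer table
#'
#' Loads the bundled primer table used for marker planting and simulated PCR.
#' The primers are synthetic stand-ins shipped with the package (see the file
#' \code{extdata/primers_synthetic.tsv}); they are not curated barcoding
#' primers.
#'
#' @return data.frame: name, marker, forward, reverse, product_min, product_max
#' @export
defaultPrimers <- function() {
  readPrimerTable(system.file("extdata", "primers_synthetic.tsv",
                              package = "skimplast", mustWork = TRUE))
}

#' @describeIn defaultPrimers read and validate a primer table (TSV with
#'   columns name, marker, forward, reverse, product_min, product_max;
#'   primers 15-35 nt).
#' @param path TSV path
#' @export
readPrimerTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "marker", "forward", "reverse", "product_min", "product_max")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("primer table lacks columns: ",
                         paste(miss, collapse = ", "))
  len <- c(nchar(tab$forward), nchar(tab$reverse))
  if (any(len < 15 | len > 35)) stop("primers must be 15-35 nt")
  if (any(tab$product_min > tab$product_max))
    stop("product_min must be <= product_max")
  tab$forward <- .sanitizeChars(tab$forward, tab$name)
  tab$reverse <- .sanitizeChars(tab$reverse, tab$name)
  tab
}

# Planted amplicon: forward primer + random core + revcomp(reverse primer).
.markerAmplicon <- function(primerRow, gc) {
  fwd <- .concretizeIupac(primerRow$forward)
  rev <- .concretizeIupac(primerRow$reverse)
  len <- floor((primerRow$product_min + primerRow$product_max) / 2)
  core <- .randomDNA(len - nchar(fwd) - nchar(rev), gc)
  paste0(fwd, core, as.character(reverseComplement(rev)))
}

#' Simulate an annotated quadripartite plastome
#'
#' Generates a random genome with the LSC / IRa / SSC / IRb layout (IRb the
#' exact reverse complement of IRa), plants rbcL and matK marker loci in the
#' LSC (matK on the minus strand) and an rdna locus in the SSC, each with
#' literal primer-binding sites from [defaultPrimers()] so simulated PCR can
#' recover them. The bases flanking the single-copy/IR boundaries are
#' constrained so the planted IR pair is exactly maximal, which lets
#' [detectInvertedRepeat()] recover the annotated intervals precisely.
#'
#' @param config a [SimConfig()]
#' @param seed RNG seed (\code{NULL} continues the current RNG stream)
#' @param primers primer table (see [readPrimerTable()])
#' @return a [PlastomeTruth-class]
#' @export
simulatePlastome <- function(config = SimConfig(), seed = config@seed,
                             primers = defaultPrimers()) {
  validObject(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config@genomeLength
  ir <- config@irLength
  ssc <- config@sscLength
  lsc <- n - 2 * ir - ssc
  gc <- config@gc

  amp <- function(marker) {
    row <- primers[primers$marker == marker, , drop = FALSE][1, ]
    .markerAmplicon(row, gc)
  }
  rbcl <- amp("rbcL"); matk <- amp("matK"); rdna <- amp("rdna")

  # marker offsets within their segment (1-based)
  o_rbcl <- max(1L, floor(lsc * 0.15))
  o_matk <- max(1L, floor(lsc * 0.55))
  o_rdna <- max(1L, floor(ssc * 0.20))
  if (o_rbcl + nchar(rbcl) > o_matk ||
      o_matk + nchar(matk) - 1 > lsc ||
      o_rdna + nchar(rdna) - 1 > ssc)
    stop("infeasible layout: markers and IRs exceed the genome length")

  lscSeq <- .randomDNA(lsc, gc)
  substr(lscSeq, o_rbcl, o_rbcl + nchar(rbcl) - 1) <- rbcl
  matkTop <- as.character(reverseComplement(matk))  # planted on minus strand
  substr(lscSeq, o_matk, o_matk + nchar(matk) - 1) <- matkTop
  sscSeq <- .randomDNA(ssc, gc)
  substr(sscSeq, o_rdna, o_rdna + nchar(rdna) - 1) <- rdna
  iraSeq <- .randomDNA(ir, gc)

  # block inward extension of the (IRa, IRb) pair: last SSC base must not be
  # the complement of the first SSC base
  if (substr(sscSeq, ssc, ssc) == .comp1(substr(sscSeq, 1, 1)))
    substr(sscSeq, ssc, ssc) <- sample(
      setdiff(BASES, .comp1(substr(sscSeq, 1, 1))), 1)

  genome <- paste0(lscSeq, iraSeq, sscSeq,
                   as.character(reverseComplement(iraSeq)))
  regions <- IRanges::IRanges(
    start = c(1, lsc + 1, lsc + ir + 1, lsc + ir + ssc + 1),
    width = c(lsc, ir, ssc, ir), names = c("LSC", "IRa", "SSC", "IRb"))
  markers <- GenomicRanges::GRanges(
    "genome",
    IRanges::IRanges(
      start = c(o_rbcl, o_matk, lsc + ir + o_rdna),
      width = c(nchar(rbcl), nchar(matk), nchar(rdna)),
      names = c("rbcL", "matK", "rdna")),
    strand = c("+", "-", "+"))
  new("PlastomeTruth", seq = Biostrings::DNAString(genome), regions = regions,
      markers = markers,
      taxon = c(genus = "SimGenus", species = "SimGenus_sp1",
                sample_id = "sim_001"))
}

# Offset of a position after applying indel events (pos, delta) upstream of it.
.shiftPos <- function(x, events) {
  if (nrow(events) == 0) return(x)
  vapply(x, function(p) p + sum(events$delta[events$pos < p]), numeric(1))
}

#' Evolve a plastome
#'
#' Applies point substitutions at an expected per-base rate and small (1-10
#' bp) insertions/deletions at \code{indelRate} to the LSC, IRa and SSC
#' segments independently, then re-imposes the inverted-repeat mirror
#' (IRb := revcomp(IRa)). Substitutions never introduce ambiguity codes.
#' Marker annotations are remapped through the indels; indels are not placed
#' inside marker loci so the loci stay structurally intact, and the 35 bp at
#' each marker end are held substitution-free, mirroring the conserved
#' flanking sites that barcoding primers rely on (the marker interior evolves
#' freely).
#'
#' @param truth a [PlastomeTruth-class]
#' @param divergence expected substitution fraction in [0, 0.3]
#' @param indelRate expected indel events per base
#' @param seed RNG seed (\code{NULL} continues the current stream)
#' @return an evolved [PlastomeTruth-class]
#' @export
evolveGenome <- function(truth, divergence, indelRate = 0, seed = NULL) {
  if (divergence < 0 || divergence > 0.3) stop("divergence must be in [0, 0.3]")
  if (!is.null(seed)) set.seed(seed)
  r <- truth@regions
  m <- truth@markers
  rs <- stats::setNames(start(r), names(r))
  re <- stats::setNames(end(r), names(r))
  segNames <- c("LSC", "IRa", "SSC")
  segs <- lapply(segNames, function(nm)
    as.character(subseq(truth@seq, rs[[nm]], re[[nm]])))
  names(segs) <- segNames

  # markers per segment, in segment-local coordinates
  segOf <- vapply(seq_along(m), function(i) {
    names(r)[which(start(m)[i] >= start(r) & end(m)[i] <= end(r))[1]]
  }, character(1))
  newMarkerStart <- numeric(length(m))
  newMarkerWidth <- width(m)
  events <- list()

  for (nm in segNames) {
    s <- segs[[nm]]
    len <- nchar(s)
    # primer-binding marker ends are conserved (barcoding primers target
    # conserved flanks); the marker interior evolves freely
    local <- which(segOf == nm)
    anchorLo <- anchorHi <- integer(0)
    if (length(local)) {
      ms <- start(m)[local] - rs[[nm]] + 1
      me <- end(m)[local] - rs[[nm]] + 1
      anchorLo <- c(anchorLo, ms, me - 34)
      anchorHi <- c(anchorHi, ms + 34, me)
    }
    conserved <- function(p) if (!length(anchorLo)) rep(FALSE, length(p)) else
      vapply(p, function(x) any(x >= anchorLo & x <= anchorHi), logical(1))
    # substitutions
    pos <- which(runif(len) < divergence)
    pos <- pos[!conserved(pos)]
    if (length(pos)) {
      ch <- strsplit(s, "")[[1]]
      ok <- ch[pos] %in% BASES
      for (p in pos[ok])
        ch[p] <- sample(setdiff(BASES, ch[p]), 1)
      s <- paste(ch, collapse = "")
    }
    # indels, kept out of marker loci
    ev <- data.frame(pos = numeric(0), delta = numeric(0))
    if (indelRate > 0) {
      ipos <- which(runif(len) < indelRate)
      if (length(local)) {
        lo <- start(m)[local] - rs[[nm]] + 1 - 12
        hi <- end(m)[local] - rs[[nm]] + 1 + 12
        protected <- vapply(ipos, function(p) any(p >= lo & p <= hi),
                            logical(1))
        ipos <- ipos[!protected]
      }
      for (p in sort(ipos, decreasing = TRUE)) {
        size <- sample.int(10, 1)
        if (runif(1) < 0.5) {  # insertion before p
          s <- paste0(substr(s, 1, p - 1), .randomDNA(size, 0.5),
                      substr(s, p, nchar(s)))
          ev <- rbind(ev, data.frame(pos = p, delta = size))
        } else if (p + size - 1 <= nchar(s)) {  # deletion of [p, p+size)
          s <- paste0(substr(s, 1, p - 1), substr(s, p + size, nchar(s)))
          ev <- rbind(ev, data.frame(pos = p, delta = -size))
        }
      }
    }
    segs[[nm]] <- s
    events[[nm]] <- ev
  }

  lens <- vapply(segs, nchar, numeric(1))
  segStartOld <- rs[segNames]
  segStartNew <- stats::setNames(cumsum(c(1, lens[-3])), segNames)

  # block inward IR extension (see simulatePlastome)
  ssc <- segs[["SSC"]]
  if (substr(ssc, nchar(ssc), nchar(ssc)) == .comp1(substr(ssc, 1, 1))) {
    substr(ssc, nchar(ssc), nchar(ssc)) <-
      sample(setdiff(BASES, .comp1(substr(ssc, 1, 1))), 1)
    segs[["SSC"]] <- ssc
  }

  for (i in seq_along(m)) {
    nm <- segOf[i]
    localStart <- start(m)[i] - segStartOld[nm] + 1
    newLocal <- .shiftPos(localStart, events[[nm]])
    newMarkerStart[i] <- segStartNew[nm] + newLocal - 1
  }

  genome <- paste0(segs$LSC, segs$IRa, segs$SSC,
                   as.character(reverseComplement(segs$IRa)))
  regions <- IRanges::IRanges(
    start = c(1, lens["LSC"] + 1, lens["LSC"] + lens["IRa"] + 1,
              lens["LSC"] + lens["IRa"] + lens["SSC"] + 1),
    width = c(lens["LSC"], lens["IRa"], lens["SSC"], lens["IRa"]),
    names = c("LSC", "IRa", "SSC", "IRb"))
  markers <- GenomicRanges::GRanges(
    "genome",
    IRanges::IRanges(start = newMarkerStart, width = newMarkerWidth,
                     names = names(m)),
    strand = GenomicRanges::strand(m))
  new("PlastomeTruth", seq = Biostrings::DNAString(genome), regions = regions,
      markers = markers, taxon = truth@taxon)
}

#' Build a taxonomically structured reference database
#'
#' Simulates a common ancestor, derives one root genome per genus at
#' \code{interGenusDivergence}, and one genome per species within each genus
#' at \code{intraGenusDivergence}. Sample ids are unique; the taxonomy table
#' maps sample_id to genus and species.
#'
#' @param config a [SimConfig()]
#' @param seed RNG seed
#' @return list with \code{genomes} (named list of [PlastomeTruth-class]) and
#'   \code{taxonomy} (data.frame: sample_id, genus, species)
#' @export
buildTaxonomyDb <- function(config = SimConfig(), seed = config@seed) {
  validObject(config)
  if (!is.null(seed)) set.seed(seed)
  ancestor <- simulatePlastome(config, seed = NULL)
  genomes <- list()
  tax <- list()
  i <- 0
  for (g in seq_len(config@nGenera)) {
    genusRoot <- evolveGenome(ancestor, config@interGenusDivergence)
    genus <- sprintf("Genus%02d", g)
    for (s in seq_len(config@speciesPerGenus)) {
      i <- i + 1
      sp <- evolveGenome(genusRoot, config@intraGenusDivergence)
      species <- sprintf("%s_sp%02d", genus, s)
      id <- sprintf("S%03d", i)
      sp@taxon <- c(genus = genus, species = species, sample_id = id)
      genomes[[id]] <- sp
      tax[[i]] <- data.frame(sample_id = id, genus = genus, species = species,
                             stringsAsFactors = FALSE)
    }
  }
  list(genomes = genomes, taxonomy = do.call(rbind, tax))
}

#' @describeIn buildTaxonomyDb draw "known unknown" query specimens: species
#'   sampled from the database (with replacement), each evolved at the
#'   intra-species divergence.
#' @param db result of [buildTaxonomyDb()]
#' @param nQueries number of query specimens
#' @param divergence intra-species substitution fraction
#' @export
simulateQueries <- function(db, nQueries, divergence = 0.003, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pick <- sample.int(length(db$genomes), nQueries, replace = TRUE)
  truths <- lapply(seq_len(nQueries), function(i) {
    q <- evolveGenome(db$genomes[[pick[i]]], divergence)
    q@taxon["sample_id"] <- sprintf("query_%03d", i)
    q
  })
  names(truths) <- vapply(truths, function(t) t@taxon[["sample_id"]],
                          character(1))
  tax <- db$taxonomy[pick, ]
  tax$sample_id <- names(truths)
  rownames(tax) <- NULL
  list(truths = truths, taxonomy = tax)
}

# Inject substitution errors at rate e into fixed-length reads.
.injectErrors <- function(seqs, e, rl) {
  if (e <= 0) return(seqs)
  k <- rbinom(length(seqs), rl, e)
  for (i in which(k > 0)) {
    pos <- sample.int(rl, k[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      if (cur %in% BASES)
        substr(seqs[i], p, p) <- sample(setdiff(BASES, cur), 1)
    }
  }
  seqs
}

#' Simulate herbarium-style paired-end reads
#'
#' Draws fragments with log-normal lengths (mean \code{fragmentMean}, sd
#' \code{fragmentSd}, truncated below at the read length) from the plastome
#' with probability \code{cpFraction} and otherwise from an independent
#' random background genome of the same GC (contaminant / nuclear model).
#' Each fragment yields a 2 x \code{readLength} pair in FR orientation with
#' per-base substitution errors at \code{perBaseError} and constant Phred
#' qualities reflecting that error probability. The realized plastome depth
#' is approximately \code{depth * cpFraction}.
#'
#' @param truth a [PlastomeTruth-class]
#' @param config a [SimConfig()]
#' @param seed RNG seed
#' @return list: \code{r1}, \code{r2} (\code{QualityScaledDNAStringSet}),
#'   \code{truthDepth} (integer per-base plastome read coverage),
#'   \code{isPlastome} (logical per pair)
#' @export
simulateReads <- function(truth, config = SimConfig(), seed = config@seed) {
  validObject(config)
  if (!is.null(seed)) set.seed(seed)
  g <- as.character(truth@seq)
  n <- nchar(g)
  rl <- config@readLength
  if (config@fragmentMean < rl)
    warning("fragment mean below read length; fragment lengths clipped")
  nPairs <- max(1L, round(config@depth * n / (2 * rl)))
  isCp <- runif(nPairs) < config@cpFraction
  bg <- .randomDNA(n, config@gc)

  cv <- config@fragmentSd / config@fragmentMean
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(config@fragmentMean) - sdlog^2 / 2
  fl <- pmin(pmax(round(rlnorm(nPairs, meanlog, sdlog)), rl), n)
  src <- ifelse(isCp, g, bg)
  starts <- floor(runif(nPairs) * (n - fl + 1)) + 1
  frag <- Biostrings::DNAStringSet(substring(src, starts, starts + fl - 1))
  flip <- runif(nPairs) < 0.5
  if (any(flip)) frag[flip] <- Biostrings::reverseComplement(frag[flip])
  r1 <- as.character(subseq(frag, 1, rl))
  r2 <- as.character(subseq(Biostrings::reverseComplement(frag), 1, rl))
  r1 <- .injectErrors(r1, config@perBaseError, rl)
  r2 <- .injectErrors(r2, config@perBaseError, rl)

  e <- config@perBaseError
  q <- if (e > 0) max(2L, min(40L, round(-10 * log10(e)))) else 40L
  qstr <- strrep(rawToChar(as.raw(q + 33L)), rl)
  ids <- sprintf("read_%06d", seq_len(nPairs))
  mk <- function(s, mate) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(s),
      Biostrings::PhredQuality(rep(qstr, length(s))))
    names(x) <- paste0(ids, "/", mate)
    x
  }
  covRanges <- IRanges::IRanges(
    start = c(starts[isCp], starts[isCp] + fl[isCp] - rl), width = rl)
  truthDepth <- as.integer(IRanges::coverage(covRanges, width = n))
  list(r1 = mk(r1, 1), r2 = mk(r2, 2), truthDepth = truthDepth,
       isPlastome = isCp)
}

#' Fragment a genome into a blind contig set
#'
#' Cuts the genome at \code{nBreaks} uniformly drawn positions; each piece is
#' independently reverse-complemented with probability \code{flipProb} and
#' dropped with probability \code{lossProb}. Contig ids and order carry no
#' information about true placement.
#'
#' @param truth a [PlastomeTruth-class]
#' @param nBreaks number of cut positions
#' @param flipProb,lossProb per-piece probabilities
#' @param seed RNG seed
#' @return \code{DNAStringSet} of contigs
#' @export
fragmentContigs <- function(truth, nBreaks, flipProb = 0, lossProb = 0,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- as.character(truth@seq)
  n <- nchar(g)
  breaks <- if (nBreaks > 0) sort(sample.int(n - 1, nBreaks)) else integer(0)
  starts <- c(1, breaks + 1)
  ends <- c(breaks, n)
  pieces <- Biostrings::DNAStringSet(substring(g, starts, ends))
  flip <- runif(length(pieces)) < flipProb
  if (any(flip)) pieces[flip] <- Biostrings::reverseComplement(pieces[flip])
  keep <- runif(length(pieces)) >= lossProb
  pieces <- pieces[keep]
  pieces <- pieces[sample.int(length(pieces))]
  names(pieces) <- sprintf("contig_%02d", seq_along(pieces))
  pieces
}

#' Extract a planted marker sequence
#'
#' Returns the marker locus sequence in amplicon orientation (reverse
#' complemented for minus-strand markers).
#'
#' @param truth a [PlastomeTruth-class]
#' @param marker one of "rbcL", "matK", "rdna"
#' @return \code{DNAString}
#' @export
markerSequence <- function(truth, marker = c("rbcL", "matK", "rdna")) {
  marker <- match.arg(marker)
  m <- truth@markers[marker]
  s <- subseq(truth@seq, GenomicRanges::start(m), GenomicRanges::end(m))
  if (as.character(GenomicRanges::strand(m)) == "-")
    s <- Biostrings::reverseComplement(s)
  s
}
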