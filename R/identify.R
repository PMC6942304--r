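#' Average common substring (ACS) distance
#'
#' Alignment-free distance built from matching statistics. With L(A,B) the
#' mean over query positions of the longest match length into B (zeros
#' floored at 1 so disjoint alphabets stay finite),
#' \deqn{d(A,B) = \log|B| / L(A,B) - 2\log|A| / (|A|+1)}
#' where the second term cancels the self-match baseline so that d(A,A) = 0.
#' The default symmetric mode returns (d(A,B) + d(B,A)) / 2.
#'
#' @param a,b DNA sequences (length >= 10)
#' @param bothStrands match on both subject strands (default TRUE)
#' @param mode "symmetric" (default) or "directed" (d(a,b) only)
#' @return the ACS distance (0 for identical sequences)
#' @export
acsDistance <- function(a, b, bothStrands = TRUE,
                        mode = c("symmetric", "directed")) {
  mode <- match.arg(mode)
  a <- .asChar(a); b <- .asChar(b)
  if (nchar(a) < 10 || nchar(b) < 10) stop("sequences must be >= 10 nt")
  .acsDistanceMatrix(a, b, bothStrands = bothStrands, mode = mode)[1, 1]
}

# Q x S matrix of ACS distances; each sequence's automaton is built once.
.acsDistanceMatrix <- function(queries, subjects, bothStrands = TRUE,
                               mode = "symmetric") {
  qc <- .asChar(queries); sc <- .asChar(subjects)
  wq <- nchar(qc); ws <- nchar(sc)
  nq <- length(qc); ns <- length(sc)
  Lqs <- cpp_acs_lbar(qc, sc, bothStrands)
  dqs <- matrix(log(ws), nq, ns, byrow = TRUE) / Lqs -
    matrix(2 * log(wq) / (wq + 1), nq, ns)
  if (mode == "directed") return(dqs)
  Lsq <- cpp_acs_lbar(sc, qc, bothStrands)
  dsq <- matrix(log(wq), ns, nq, byrow = TRUE) / Lsq -
    matrix(2 * log(ws) / (ws + 1), ns, nq)
  (dqs + t(dsq)) / 2
}

#' Rank a database by ACS distance
#'
#' Computes the ACS distance from the query to every database sequence and
#' returns hits sorted by ascending distance, ties broken by subject id.
#'
#' @param query query sequence
#' @param db named \code{DNAStringSet} (or named character vector)
#' @param taxonomy optional data.frame (sample_id, genus, species)
#' @param marker marker class label carried in the result
#' @param queryId query identifier
#' @param bothStrands,mode passed to [acsDistance()]
#' @return a [MatchRanking-class]
#' @export
rankDatabase <- function(query, db, taxonomy = NULL, marker = "cpDNA",
                         queryId = "query", bothStrands = TRUE,
                         mode = "symmetric") {
  if (length(db) == 0) stop("empty database")
  ids <- names(db) %||% sprintf("subject_%03d", seq_along(db))
  q <- .asChar(query)
  dist <- .acsDistanceMatrix(q, db, bothStrands = bothStrands, mode = mode)[1, ]
  h <- data.frame(subject_id = ids, distance = dist, stringsAsFactors = FALSE)
  if (!is.null(taxonomy)) {
    m <- match(h$subject_id, taxonomy$sample_id)
    h$genus <- taxonomy$genus[m]
    h$species <- taxonomy$species[m]
  } else {
    h$genus <- NA_character_
    h$species <- NA_character_
  }
  h <- h[order(h$distance, h$subject_id), ]
  h$rank <- seq_len(nrow(h))
  rownames(h) <- NULL
  new("MatchRanking", queryId = queryId, marker = marker,
      hits = h[, c("subject_id", "genus", "species", "distance", "rank")])
}

# Amplicons from forward-strand primer sites on one template orientation.
.pcrOneStrand <- function(templ, fwd, rev, productMin, productMax,
                          maxMismatch) {
  n <- nchar(templ)
  fs <- cpp_pcr_sites(templ, fwd, maxMismatch)
  # reverse-primer sites are found by scanning the template's reverse
  # complement, which keeps the 3'-end anchor on the primer's own 3' end
  rsAnchored <- cpp_pcr_sites(as.character(reverseComplement(templ)), rev,
                              maxMismatch)
  revStarts <- n - (rsAnchored$pos + nchar(rev))
  out <- list()
  for (i in seq_along(fs$pos)) {
    f <- fs$pos[i]
    for (j in seq_along(revStarts)) {
      rstart <- revStarts[j]
      e <- rstart + nchar(rev)             # 0-based exclusive amplicon end
      plen <- e - f
      if (rstart <= f) next
      if (plen < productMin || plen > productMax) next
      out[[length(out) + 1L]] <- data.frame(
        start = f + 1L, end = e, length = plen,
        fwd_mismatches = fs$mismatches[i],
        rev_mismatches = rsAnchored$mismatches[j])
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Simulated PCR
#'
#' Finds all amplicons a primer pair would produce from a template. Primer
#' bases match template bases when their IUPAC possibility sets intersect
#' (degenerate primer codes are honoured); a fully ambiguous template base
#' (N) binds nothing. Up to \code{maxMismatch} mismatches are allowed per
#' primer, but the 3 bases at each primer's 3' end must match exactly. Both
#' template strands are scanned; the amplicon spans the forward primer 5' end
#' to the reverse primer 5' end, inclusive.
#'
#' @param template template sequence (\code{DNAString} or character)
#' @param primers one primer pair: a one-row data.frame (or list) with
#'   forward, reverse, product_min, product_max (see [readPrimerTable()])
#' @param maxMismatch per-primer mismatch budget (default 2)
#' @param templateId id recorded in the result
#' @return data.frame: template_id, start, end, strand, length,
#'   fwd_mismatches, rev_mismatches, sequence (primer-to-primer, in amplicon
#'   orientation); zero rows when nothing amplifies
#' @export
insilicoPcr <- function(template, primers, maxMismatch = 2L,
                        templateId = "template") {
  s <- toupper(.asChar(template))
  n <- nchar(s)
  fwd <- toupper(primers$forward)
  rev <- toupper(primers$reverse)
  pmin_ <- primers$product_min
  pmax_ <- primers$product_max
  res <- list()
  plus <- .pcrOneStrand(s, fwd, rev, pmin_, pmax_, maxMismatch)
  if (!is.null(plus)) {
    plus$strand <- "+"
    plus$sequence <- substring(s, plus$start, plus$end)
    res[[1]] <- plus
  }
  src <- as.character(reverseComplement(s))
  minus <- .pcrOneStrand(src, fwd, rev, pmin_, pmax_, maxMismatch)
  if (!is.null(minus)) {
    minus$sequence <- substring(src, minus$start, minus$end)
    st <- minus$start
    minus$start <- n - minus$end + 1L
    minus$end <- n - st + 1L
    minus$strand <- "-"
    res[[2]] <- minus
  }
  if (!length(res))
    return(data.frame(template_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      length = integer(0), fwd_mismatches = integer(0),
                      rev_mismatches = integer(0), sequence = character(0)))
  out <- do.call(rbind, res)
  out$template_id <- templateId
  out <- out[order(out$start, out$strand), c(
    "template_id", "start", "end", "strand", "length", "fwd_mismatches",
    "rev_mismatches", "sequence")]
  rownames(out) <- NULL
  out
}

#' Extract a barcode by simulated PCR
#'
#' Tries the primer pairs listed for the marker in table order and returns
#' the first amplicon found (primers included). The chosen pair and mismatch
#' counts are attached as attributes. \code{NULL} when no pair amplifies.
#'
#' @param assembly assembled sequence
#' @param marker barcode marker name (must appear in the primer table)
#' @param primerTable data.frame from [readPrimerTable()] /
#'   [defaultPrimers()]
#' @param maxMismatch per-primer mismatch budget
#' @return \code{DNAString} or \code{NULL}
#' @export
extractBarcode <- function(assembly, marker, primerTable = defaultPrimers(),
                           maxMismatch = 2L) {
  rows <- primerTable[primerTable$marker == marker, , drop = FALSE]
  if (nrow(rows) == 0) stop("unknown marker '", marker, "'")
  for (i in seq_len(nrow(rows))) {
    amp <- insilicoPcr(assembly, rows[i, ], maxMismatch = maxMismatch)
    if (nrow(amp) > 0) {
      out <- Biostrings::DNAString(amp$sequence[1])
      attr(out, "primer_name") <- rows$name[i]
      attr(out, "fwd_mismatches") <- amp$fwd_mismatches[1]
      attr(out, "rev_mismatches") <- amp$rev_mismatches[1]
      return(out)
    }
  }
  NULL
}

#' Evaluate identification accuracy
#'
#' Ranks every query against the database and scores top-1 genus and species
#' agreement with the morphology-style truth labels.
#'
#' @param queries \code{DNAStringSet} (or character vector) of query
#'   sequences
#' @param trueGenus,trueSpecies truth labels, parallel to \code{queries}
#' @param db named \code{DNAStringSet} database
#' @param taxonomy taxonomy data.frame (sample_id, genus, species)
#' @param marker marker class label
#' @return list: genus_agreement, species_agreement (fractions), table
#'   (per-query top-3 hits with distances and agreement flags)
#' @export
evaluateIdentification <- function(queries, trueGenus, trueSpecies, db,
                                   taxonomy, marker = "cpDNA") {
  if (length(queries) == 0) stop("no queries")
  qids <- names(queries) %||% sprintf("query_%03d", seq_along(queries))
  ids <- names(db) %||% sprintf("subject_%03d", seq_along(db))
  D <- .acsDistanceMatrix(queries, db, bothStrands = TRUE)
  rows <- lapply(seq_along(queries), function(i) {
    h <- data.frame(subject_id = ids, distance = D[i, ],
                    stringsAsFactors = FALSE)
    m <- match(h$subject_id, taxonomy$sample_id)
    h$genus <- taxonomy$genus[m]
    h$species <- taxonomy$species[m]
    h <- h[order(h$distance, h$subject_id), ]
    top3 <- utils::head(h, 3)
    data.frame(query_id = qids[i], true_genus = trueGenus[i],
               true_species = trueSpecies[i], top_subject = h$subject_id[1],
               top_genus = h$genus[1], top_species = h$species[1],
               top_distance = h$distance[1],
               top3 = paste(sprintf("%s(%.4g)", top3$subject_id,
                                    top3$distance), collapse = ";"),
               genus_ok = identical(h$genus[1], trueGenus[i]),
               species_ok = identical(h$species[1], trueSpecies[i]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(genus_agreement = mean(tab$genus_ok),
       species_agreement = mean(tab$species_ok), table = tab)
}
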