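#' Choose the best guiding reference
#'
#' Scores every candidate reference by the union length of the subject
#' intervals of its contig chains ("covered the most sequence"), breaking
#' ties by fewer contigs used, then by lexicographic reference id. Invariant
#' to the order of the input map.
#'
#' @param alignmentsByRef named list: ref_id -> alignment data.frame from
#'   [alignContigs()]
#' @return list: ref_id, covered_bases, n_contigs
#' @export
selectReference <- function(alignmentsByRef) {
  alignmentsByRef <- Filter(function(a) nrow(a) > 0, alignmentsByRef)
  if (!length(alignmentsByRef)) stop("no reference has any alignment")
  stats <- lapply(names(alignmentsByRef), function(id) {
    a <- alignmentsByRef[[id]]
    a <- a[!duplicated(a$contig_id), , drop = FALSE]  # one placement per contig
    cov <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(a$s_start, a$s_end))))
    data.frame(ref_id = id, covered_bases = cov,
               n_contigs = length(unique(a$contig_id)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, stats)
  tab <- tab[order(-tab$covered_bases, tab$n_contigs, tab$ref_id), ]
  as.list(tab[1, ])
}

# Resolve tied placements: unambiguous contigs are placed first (largest
# matched_bases first); a tied contig takes the placement least covered by
# already-placed contigs, then the earliest subject start.
.resolvePlacements <- function(alignments) {
  byContig <- split(alignments, alignments$contig_id)
  nPlace <- vapply(byContig, nrow, integer(1))
  score <- vapply(byContig, function(a) max(a$matched_bases), numeric(1))
  ord <- names(byContig)[order(nPlace, -score)]
  occupied <- IRanges::IRanges()
  chosen <- list()
  for (id in ord) {
    a <- byContig[[id]]
    if (nrow(a) > 1) {
      ov <- vapply(seq_len(nrow(a)), function(i) {
        sum(IRanges::width(IRanges::intersect(
          IRanges::IRanges(a$s_start[i], a$s_end[i]), occupied)))
      }, numeric(1))
      a <- a[order(ov, a$s_start), , drop = FALSE]
    }
    pick <- a[1, , drop = FALSE]
    occupied <- IRanges::union(occupied,
                               IRanges::IRanges(pick$s_start, pick$s_end))
    chosen[[id]] <- pick
  }
  out <- do.call(rbind, chosen)
  out[order(out$s_start, out$s_end), , drop = FALSE]
}

#' Reference-guided scaffolding of contigs
#'
#' Orders contigs by their subject start on the chosen reference, reverse
#' complements minus-strand placements, and connects neighbours: subject
#' overlaps are merged by trimming the lower-\code{identity_proxy} contig's
#' overlapping bases; gaps are N-filled to the subject gap size (policy
#' \code{"n-fill"}) or closed by direct concatenation (\code{"direct"});
#' abutting contigs are joined directly. Contigs whose subject interval is
#' fully contained in another's are dropped with a warning. Tied placements
#' from [alignContigs()] are resolved against already-placed contigs.
#'
#' @param contigs \code{DNAStringSet} holding every aligned contig
#' @param alignments data.frame from [alignContigs()] against one reference
#' @param referenceLength length of that reference (bp)
#' @param gapPolicy "n-fill" (default) or "direct"
#' @return a [Draft-class]
#' @export
scaffoldContigs <- function(contigs, alignments, referenceLength,
                            gapPolicy = c("n-fill", "direct")) {
  gapPolicy <- match.arg(gapPolicy)
  if (is.null(alignments) || nrow(alignments) == 0)
    stop("no alignments to scaffold")
  for (col in c("q_start", "q_end", "s_start", "s_end"))
    alignments[[col]] <- as.integer(alignments[[col]])
  pl <- .resolvePlacements(alignments)

  # drop placements fully contained in another placement's subject interval
  keep <- rep(TRUE, nrow(pl))
  for (i in seq_len(nrow(pl))) {
    inside <- pl$s_start <= pl$s_start[i] & pl$s_end >= pl$s_end[i]
    inside[i] <- FALSE
    inside <- inside & (pl$s_end - pl$s_start > pl$s_end[i] - pl$s_start[i] |
                          seq_len(nrow(pl)) < i)
    if (any(inside & keep)) {
      warning("contig '", pl$contig_id[i],
              "' is contained within another placement; dropped")
      keep[i] <- FALSE
    }
  }
  pl <- pl[keep, , drop = FALSE]

  pieces <- character(0)
  seg <- list()
  jun <- list()
  pos <- 0L
  prevSend <- NA_integer_
  prevTail <- 0L
  prevIdent <- NA_real_
  for (i in seq_len(nrow(pl))) {
    p <- pl[i, ]
    cs <- .asChar(contigs[[p$contig_id]])
    L <- nchar(cs)
    oriented <- if (p$strand == "-") reverseComplement(cs) else cs
    headLen <- if (p$strand == "+") p$q_start - 1L else L - p$q_end
    tailLen <- if (p$strand == "+") L - p$q_end else p$q_start - 1L
    trimHead <- 0L
    if (i > 1L) {
      gapSub <- p$s_start - prevSend - 1L
      eff <- gapSub - prevTail - headLen
      if (eff > 0L) {
        if (gapPolicy == "n-fill") {
          pieces <- c(pieces, strrep("N", eff))
          jun[[length(jun) + 1L]] <- data.frame(kind = "gap-N",
                                                position = pos + 1L,
                                                size = eff)
          pos <- pos + eff
        } else {
          jun[[length(jun) + 1L]] <- data.frame(kind = "direct",
                                                position = pos + 1L,
                                                size = eff)
        }
      } else if (eff == 0L) {
        jun[[length(jun) + 1L]] <- data.frame(kind = "direct",
                                              position = pos + 1L, size = 0L)
      } else {
        ov <- -eff
        if (!is.na(prevIdent) && prevIdent >= p$identity_proxy) {
          trimHead <- min(ov, nchar(oriented) - 1L)
        } else {
          # trim the previous (lower-identity) contig's tail
          lastSeg <- seg[[length(seg)]]
          cut <- min(ov, lastSeg$d_end - lastSeg$d_start)
          pieces[length(pieces)] <-
            substr(pieces[length(pieces)], 1L,
                   nchar(pieces[length(pieces)]) - cut)
          lastSeg$d_end <- lastSeg$d_end - cut
          if (lastSeg$strand == "+") lastSeg$q_end <- lastSeg$q_end - cut
          else lastSeg$q_start <- lastSeg$q_start + cut
          seg[[length(seg)]] <- lastSeg
          pos <- pos - cut
        }
        jun[[length(jun) + 1L]] <- data.frame(kind = "overlap-merged",
                                              position = pos + 1L, size = ov)
      }
    }
    piece <- substr(oriented, 1L + trimHead, nchar(oriented))
    pieces <- c(pieces, piece)
    dStart <- pos + 1L
    pos <- pos + nchar(piece)
    qs <- if (p$strand == "+") 1L + trimHead else 1L
    qe <- if (p$strand == "+") L else L - trimHead
    seg[[length(seg) + 1L]] <- data.frame(
      contig_id = p$contig_id, q_start = qs, q_end = qe, strand = p$strand,
      d_start = dStart, d_end = pos, stringsAsFactors = FALSE)
    prevSend <- max(prevSend, p$s_end, na.rm = TRUE)
    prevTail <- tailLen
    prevIdent <- p$identity_proxy
  }
  segments <- do.call(rbind, seg)
  junctions <- if (length(jun)) do.call(rbind, jun) else
    data.frame(kind = character(0), position = integer(0), size = integer(0))
  new("Draft", seq = Biostrings::DNAString(paste(pieces, collapse = "")),
      segments = segments, junctions = junctions,
      refId = alignments$ref_id[1])
}

.readPool <- function(reads) {
  if (is.list(reads)) c(.asChar(reads$r1), .asChar(reads$r2))
  else .asChar(reads)
}

# Median pseudo-mapping depth of reads over a contig set (contigs joined by
# single-N separators; separator positions excluded).
.contigSetDepth <- function(reads, contigs, k = 31L) {
  cs <- .asChar(contigs)
  cs <- cs[nchar(cs) >= k]
  if (!length(cs)) return(0)
  asm <- paste(cs, collapse = "N")
  depth <- cpp_depth(.readPool(reads), asm, as.integer(k))
  w <- nchar(cs)
  sepPos <- cumsum(w[-length(w)] + 1L)
  if (length(sepPos)) depth <- depth[-sepPos]
  stats::median(depth)
}

#' Multi-parameter de novo assembly sweep
#'
#' Runs a pluggable assembler over paired (k-mer, coverage cut-off) rounds in
#' plan order. A round is accepted when the total length of contigs matching
#' any database reference reaches \code{minTotalLength} and the median
#' pseudo-mapping depth of the reads over the contigs reaches
#' \code{minKmerCoverage}; the sweep then stops with \code{mode = "de-novo"}.
#' If every round fails, the round with the greatest plastid-matching length
#' is returned with \code{mode = "reference-guided"} (the caller then
#' scaffolds it against the database). A failing assembler call marks its
#' round failed and the sweep continues.
#'
#' @param reads list with \code{r1}/\code{r2} (or a flat read set); passed to
#'   the assembler and used for depth assessment
#' @param assembler callback \code{function(reads, k, covCutoff)} returning a
#'   \code{DNAStringSet} of contigs (seam for an external assembler)
#' @param plan a [SweepPlan()]
#' @param referenceDb \code{DNAStringSet} of database references
#' @param minAnchor anchor length used to decide "plastid-matching"
#' @return list: contigs, mode, round, provenance (one row per round)
#' @export
runParameterSweep <- function(reads, assembler, plan = SweepPlan(),
                              referenceDb, minAnchor = 20L) {
  validObject(plan)
  if (!is.function(assembler)) stop("assembler must be a function")
  minTotal <- if (is.na(plan@minTotalLength))
    0.8 * stats::median(Biostrings::width(referenceDb))
  else plan@minTotalLength
  prov <- list()
  best <- NULL
  bestLen <- -1
  for (r in seq_along(plan@kmerValues)) {
    k <- plan@kmerValues[r]
    cc <- plan@covCutoffs[r]
    contigs <- tryCatch(assembler(reads, k, cc), error = function(e) e)
    if (inherits(contigs, "error") || length(contigs) == 0) {
      prov[[r]] <- data.frame(round = r, k = k, cov_cutoff = cc, failed = TRUE,
                              n_contigs = 0L, total_match_len = 0,
                              median_depth = NA_real_, accepted = FALSE)
      next
    }
    if (is.null(names(contigs)))
      names(contigs) <- sprintf("contig_%02d", seq_along(contigs))
    matchedIds <- character(0)
    for (ri in seq_along(referenceDb)) {
      aln <- suppressWarnings(
        alignContigs(contigs, referenceDb[ri], minLen = minAnchor))
      matchedIds <- union(matchedIds, aln$contig_id)
    }
    totalLen <- sum(Biostrings::width(contigs)[names(contigs) %in% matchedIds])
    medDepth <- .contigSetDepth(reads, contigs)
    accepted <- totalLen >= minTotal && medDepth >= plan@minKmerCoverage
    prov[[r]] <- data.frame(round = r, k = k, cov_cutoff = cc, failed = FALSE,
                            n_contigs = length(contigs),
                            total_match_len = totalLen,
                            median_depth = medDepth, accepted = accepted)
    if (accepted) {
      return(list(contigs = contigs, mode = "de-novo", round = r,
                  provenance = do.call(rbind, prov)))
    }
    if (totalLen > bestLen) { bestLen <- totalLen; best <- contigs }
  }
  list(contigs = best, mode = "reference-guided",
       round = if (bestLen >= 0) which.max(vapply(prov, function(p)
         if (p$failed) -1 else p$total_match_len, numeric(1))) else NA_integer_,
       provenance = do.call(rbind, prov))
}
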