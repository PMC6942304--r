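#' Matching statistics
#'
#' For each query position i, the length of the longest prefix of
#' \code{query[i:]} that occurs exactly somewhere in the subject (on either
#' strand when \code{bothStrands}). Ambiguity codes match nothing, so query
#' positions holding them yield 0 and no match crosses them. Satisfies the
#' descent property \code{ms[i+1] >= ms[i] - 1}.
#'
#' @param query,subject DNA sequences (character or \code{XString(Set)})
#' @param bothStrands also match against the subject's reverse complement
#' @return integer vector, one entry per query position
#' @examples
#' matchingStatistics("AAA", "AA", bothStrands = FALSE)  # 2 2 1
#' @export
matchingStatistics <- function(query, subject, bothStrands = TRUE) {
  query <- .asChar(query); subject <- .asChar(subject)
  if (!nzchar(query)) stop("query must be non-empty")
  if (!length(subject) || !nzchar(subject)) stop("empty subject index")
  cpp_matching_stats(query, subject, bothStrands)
}

#' Maximal exact matches (MEMs)
#'
#' All exact matches of length >= \code{minLen} between query and subject,
#' on both strands, that cannot be extended in either direction. Subject
#' starts refer to the matched interval on the subject top strand.
#'
#' @param query,subject DNA sequences
#' @param minLen minimum match length (>= 2; default 20)
#' @return data.frame (1-based): q_start, s_start, length, strand
#' @export
findMEMs <- function(query, subject, minLen = 20L) {
  if (minLen < 2) stop("minLen must be >= 2")
  df <- cpp_mems(.asChar(query), .asChar(subject), as.integer(minLen), TRUE)
  df$q_start <- df$q_start + 1L
  df$s_start <- df$s_start + 1L
  df <- df[order(df$q_start, df$s_start, df$strand, df$length), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Longest colinear chains over anchors given in chain coordinates (q0, s0,
# len; 0-based, both increasing along the chain). Anchors must not overlap in
# either coordinate within a chain and consecutive gaps must be <= maxGap.
# Returns every chain attaining the maximum total anchor length.
.chainAnchors <- function(q0, s0, len, maxGap) {
  n <- length(q0)
  ord <- order(q0, s0)
  q0 <- q0[ord]; s0 <- s0[ord]; len <- len[ord]
  score <- len
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      gq <- q0[i] - (q0[j] + len[j])
      gs <- s0[i] - (s0[j] + len[j])
      if (gq < 0 || gs < 0 || gq > maxGap || gs > maxGap) next
      cand <- score[j] + len[i]
      if (cand > score[i]) { score[i] <- cand; prev[i] <- j }
    }
  }
  best <- max(score)
  lapply(which(score == best), function(e) {
    idx <- integer(0)
    while (!is.na(e)) { idx <- c(e, idx); e <- prev[e] }
    list(idx = ord[idx], score = best)
  })
}

#' Align contigs to a reference by MEM anchoring and chaining
#'
#' Finds MEMs between each contig and the reference, chains them per strand
#' by the longest colinear chain (weight = total anchor length, coordinate
#' gaps <= \code{maxGap}, no overlaps within the chain) and reports the best
#' chain per contig. When several placements tie (typical for fragments
#' wholly inside an inverted-repeat copy) all tied chains are reported with
#' \code{tied = TRUE}; [scaffoldContigs()] resolves them. Contigs shorter
#' than \code{minLen} are anchored by full-length exact matches instead.
#' Contigs with no chain are omitted.
#'
#' @param contigs \code{DNAStringSet} (named)
#' @param reference a single reference sequence (\code{DNAString} or
#'   character); its name is used as \code{ref_id}
#' @param minLen minimum anchor length (default 20)
#' @param maxGap maximum anchor gap in either coordinate (bp)
#' @return data.frame (1-based): contig_id, ref_id, q_start, q_end, s_start,
#'   s_end, strand, matched_bases, identity_proxy, n_anchors, tied
#' @export
alignContigs <- function(contigs, reference, minLen = 20L, maxGap = 5000L) {
  refChar <- .asChar(reference)
  if (length(refChar) != 1) stop("reference must be a single sequence")
  if (nchar(refChar) < minLen) stop("reference shorter than minLen")
  refId <- names(reference) %||% "ref"
  refLen <- nchar(refChar)
  if (is.null(names(contigs)))
    names(contigs) <- sprintf("contig_%02d", seq_along(contigs))
  rows <- list()
  for (ci in seq_along(contigs)) {
    qChar <- .asChar(contigs[ci])
    qLen <- nchar(qChar)
    # a contig shorter than minLen can only anchor as a full-length exact
    # match; its (often tied) placements are resolved during scaffolding
    effMin <- max(2L, min(as.integer(minLen), qLen))
    mems <- cpp_mems(qChar, refChar, effMin, TRUE)
    if (nrow(mems) == 0) next
    chains <- list()
    for (st in c("+", "-")) {
      a <- mems[mems$strand == st, , drop = FALSE]
      if (nrow(a) == 0) next
      sChain <- if (st == "+") a$s_start else refLen - (a$s_start + a$length)
      for (ch in .chainAnchors(a$q_start, sChain, a$length, maxGap)) {
        sel <- a[ch$idx, , drop = FALSE]
        sTop <- range(c(sel$s_start, sel$s_start + sel$length - 1L))
        chains[[length(chains) + 1L]] <- data.frame(
          contig_id = names(contigs)[ci], ref_id = refId,
          q_start = min(sel$q_start) + 1L,
          q_end = max(sel$q_start + sel$length - 1L) + 1L,
          s_start = sTop[1] + 1L, s_end = sTop[2] + 1L, strand = st,
          matched_bases = ch$score,
          n_anchors = nrow(sel), stringsAsFactors = FALSE)
      }
    }
    if (!length(chains)) next
    df <- do.call(rbind, chains)
    df <- df[df$matched_bases == max(df$matched_bases), , drop = FALSE]
    df <- unique(df)
    if (nrow(df) > 1 && length(unique(df$strand)) > 1 &&
        max(df$matched_bases) < 0.9 * qLen)
      warning("contig '", names(contigs)[ci],
              "' has equal-score chains on both strands (possible chimera); ",
              "reporting all tied chains")
    df$identity_proxy <- df$matched_bases / (df$q_end - df$q_start + 1L)
    df$tied <- nrow(df) > 1
    rows[[length(rows) + 1L]] <- df
  }
  if (!length(rows))
    return(data.frame(contig_id = character(0), ref_id = character(0),
                      q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      strand = character(0), matched_bases = integer(0),
                      n_anchors = integer(0), identity_proxy = numeric(0),
                      tied = logical(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$s_start, out$contig_id), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("contig_id", "ref_id", "q_start", "q_end", "s_start", "s_end",
          "strand", "matched_bases", "identity_proxy", "n_anchors", "tied")]
}
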