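.asChar <- function(x) {
  if (is.character(x)) x else as.character(x)
}

.checkK <- function(k, maxLen = Inf) {
  if (k %% 2 == 0) stop("k must be odd (canonical k-mers)")
  if (k > 31) stop("k must be <= 31")
  if (k > maxLen) stop("k exceeds the sequence length")
  invisible(k)
}

#' Trim 3' adapter sequence
#'
#' Removes, from each read, the best-scoring suffix-overlapping-prefix
#' occurrence of the adapter (mismatches up to \code{maxErrorRate} of the
#' aligned length, no indels) together with everything 3' of it. Qualities
#' are trimmed in lockstep; reads trimmed to length 0 are dropped.
#'
#' @param reads \code{DNAStringSet} or \code{QualityScaledDNAStringSet}
#' @param adapter adapter sequence (plain DNA)
#' @param minOverlap minimum adapter overlap considered (default 3)
#' @param maxErrorRate maximum mismatch fraction of the aligned length
#' @return trimmed reads, same class as the input
#' @export
trimAdapters <- function(reads, adapter, minOverlap = 3L, maxErrorRate = 0.1) {
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  keep <- cpp_trim_positions(.asChar(reads), toupper(adapter),
                             as.integer(minOverlap), maxErrorRate)
  out <- subseq(reads, 1L, pmin(keep, Biostrings::width(reads)))
  out[keep > 0L]
}

#' Two-pass digital normalization of read pairs
#'
#' Pass 1 builds a canonical k-mer spectrum over both mates of every pair;
#' pass 2 computes each pair's median k-mer count and discards the pair if
#' the median is below \code{low} (error/contaminant-like) or above
#' \code{high}. Pairs with median in (\code{target}, \code{high}] are kept
#' with probability \code{target}/median. Output pairs are an unmodified
#' subset of the input.
#'
#' @param r1,r2 mate sequences (parallel \code{DNAStringSet} /
#'   \code{QualityScaledDNAStringSet})
#' @param k k-mer size (odd, <= 31; default 31)
#' @param low,high discard cut-offs on the pair median k-mer count
#' @param target downsampling target coverage
#' @param seed RNG seed for the downsampling draw
#' @return list: \code{r1}, \code{r2} (retained subset), \code{medians},
#'   \code{kept} (logical over input pairs)
#' @export
normalizeKmerDepth <- function(r1, r2, k = 31L, low = 10, high = 500,
                               target = 100, seed = NULL) {
  if (length(r1) != length(r2)) stop("r1 and r2 must be parallel")
  .checkK(k, min(Biostrings::width(r1), Biostrings::width(r2)))
  if (!is.null(seed)) set.seed(seed)
  med <- cpp_pair_median_kmer(.asChar(r1), .asChar(r2), as.integer(k))
  kept <- !is.na(med) & med >= low & med <= high
  down <- kept & med > target
  if (any(down))
    kept[down] <- runif(sum(down)) < target / med[down]
  list(r1 = r1[kept], r2 = r2[kept], medians = med, kept = kept)
}

.qualInts <- function(x) {
  if (is(x, "QualityScaledXStringSet"))
    as(Biostrings::quality(x), "IntegerList")
  else
    IRanges::IntegerList(lapply(Biostrings::width(x), function(w)
      rep.int(30L, w)))
}

#' Merge overlapping read pairs
#'
#' Orients mate 2 into fragment coordinates (reverse complement) and finds
#' the best suffix/prefix overlap by matching bases (no indels), requiring
#' overlap >= \code{minOverlap} and a mismatch rate <= \code{maxMismatchRate}.
#' At disagreeing overlap positions the higher-quality base is taken. A tie
#' between two candidate overlap lengths leaves the pair unmerged.
#'
#' @param r1,r2 mate sequences (parallel sets; qualities used when present)
#' @param minOverlap minimum overlap length (default 12)
#' @param maxMismatchRate maximum mismatch fraction of the overlap
#' @return list: \code{merged} (merged fragments), \code{unmergedR1},
#'   \code{unmergedR2}
#' @export
mergePairs <- function(r1, r2, minOverlap = 12L, maxMismatchRate = 0.1) {
  if (length(r1) != length(r2)) stop("r1 and r2 must be parallel")
  r2rc <- Biostrings::reverseComplement(r2)
  res <- cpp_overlap_merge(.asChar(r1), .asChar(r2rc),
                           as.integer(minOverlap), maxMismatchRate)
  doMerge <- res$olen >= minOverlap & !res$ambiguous
  hasQual <- is(r1, "QualityScaledXStringSet") &&
    is(r2, "QualityScaledXStringSet")
  q1 <- .qualInts(r1)
  q2 <- .qualInts(r2rc)
  s1 <- .asChar(r1)
  s2 <- .asChar(r2rc)
  merged <- character(0)
  mergedQ <- character(0)
  mnames <- character(0)
  for (i in which(doMerge)) {
    o <- res$olen[i]
    l1 <- nchar(s1[i]); l2 <- nchar(s2[i])
    a <- substr(s1[i], l1 - o + 1, l1)
    b <- substr(s2[i], 1, o)
    qa <- q1[[i]][(l1 - o + 1):l1]
    qb <- q2[[i]][1:o]
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    useB <- ca != cb & qb > qa
    ov <- ca; ov[useB] <- cb[useB]
    qo <- ifelse(ca == cb, pmax(qa, qb), ifelse(useB, qb, qa))
    merged <- c(merged, paste0(substr(s1[i], 1, l1 - o),
                               paste(ov, collapse = ""),
                               substr(s2[i], o + 1, l2)))
    qv <- c(q1[[i]][seq_len(l1 - o)], qo, q2[[i]][seq_len(l2 - o) + o])
    mergedQ <- c(mergedQ, rawToChar(as.raw(pmin(qv, 60L) + 33L)))
    mnames <- c(mnames, sub("/[12]$", "", names(r1)[i] %||% as.character(i)))
  }
  mergedSet <- if (hasQual) {
    Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(merged), Biostrings::PhredQuality(mergedQ))
  } else Biostrings::DNAStringSet(merged)
  if (length(merged)) names(mergedSet) <- mnames
  list(merged = mergedSet, unmergedR1 = r1[!doMerge], unmergedR2 = r2[!doMerge])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pseudo-mapping depth estimate
#'
#' Every canonical read k-mer that occurs exactly once in the assembly
#' increments the depth of the k assembly bases it covers. Raw k-mer-cover
#' depth is reported (no k correction), with its mean and median.
#' Deterministic and invariant to read order.
#'
#' @param reads read sequences (any \code{XStringSet} or character)
#' @param assembly a single assembly sequence
#' @param k k-mer size (odd, <= 31; default 31)
#' @return list: \code{depth} (integer per-base), \code{mean}, \code{median}
#' @export
estimateDepth <- function(reads, assembly, k = 31L) {
  assembly <- .asChar(assembly)
  if (length(assembly) != 1) stop("assembly must be a single sequence")
  if (nchar(assembly) < k) stop("assembly is shorter than k")
  .checkK(k)
  depth <- cpp_depth(.asChar(reads), assembly, as.integer(k))
  list(depth = depth, mean = mean(depth), median = stats::median(depth))
}

#' Canonical k-mer spectrum
#'
#' Counts canonical k-mers (lexicographic minimum of a k-mer and its reverse
#' complement) across a set of sequences; k-mers containing ambiguity codes
#' are skipped.
#'
#' @param seqs sequences (\code{XStringSet} or character)
#' @param k odd k-mer size <= 31
#' @return data.frame: kmer, count
#' @export
kmerSpectrum <- function(seqs, k = 31L) {
  .checkK(k)
  res <- cpp_kmer_spectrum(.asChar(seqs), as.integer(k))
  data.frame(kmer = res$kmer, count = res$count, stringsAsFactors = FALSE)
}
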