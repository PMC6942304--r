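#' Assembly length-ratio error
#'
#' \code{|ln(assemblyLength / refMatchLength)|}. The natural log makes the
#' 0.1 threshold correspond to roughly a +/- 10% length discrepancy
#' (e^0.1 - 1 = 10.5%, 1 - e^-0.1 = 9.5%), and missing sequence counts
#' slightly more towards the error than the same amount of extra sequence.
#' Scale invariant: error(k*a, k*b) == error(a, b).
#'
#' @param assemblyLength,refMatchLength positive lengths (bp); vectorised
#' @return non-negative error value(s)
#' @examples
#' assemblyError(165000, 150000)  # 0.0953
#' assemblyError(135000, 150000)  # 0.1054 -- missing sequence weighs more
#' @export
assemblyError <- function(assemblyLength, refMatchLength) {
  if (any(assemblyLength <= 0) || any(refMatchLength <= 0))
    stop("lengths must be positive")
  abs(log(assemblyLength / refMatchLength))
}

#' Good/poor assembly classification
#'
#' An assembly with an error of \code{threshold} (default 0.1) or greater is
#' classified poor; the boundary is inclusive.
#'
#' @param error non-negative error value(s) from [assemblyError()]
#' @param threshold classification threshold (default 0.1)
#' @return character vector of "good"/"poor"
#' @export
classifyAssembly <- function(error, threshold = 0.1) {
  if (any(error < 0)) stop("error must be >= 0")
  ifelse(error >= threshold, "poor", "good")
}

GC_WEIGHT <- c(A = 0, C = 1, G = 1, T = 0, S = 1, W = 0, R = 0.5, Y = 0.5,
               K = 0.5, M = 0.5, N = 0.5, B = 2 / 3, V = 2 / 3, D = 1 / 3,
               H = 1 / 3)

#' GC content
#'
#' Fraction of G+C over the full sequence length. Ambiguity codes contribute
#' the expected GC among their possibilities (S = 1, W = 0, R/Y/K/M/N = 0.5,
#' B/V = 2/3, D/H = 1/3), which keeps the statistic deterministic and
#' length-preserving.
#'
#' @param seq DNA sequence (character or \code{XString})
#' @return GC fraction in [0, 1]
#' @export
gcContent <- function(seq) {
  s <- .asChar(seq)
  if (length(s) != 1 || !nzchar(s)) stop("seq must be a single non-empty sequence")
  counts <- table(strsplit(toupper(s), "")[[1]])
  bad <- setdiff(names(counts), names(GC_WEIGHT))
  if (length(bad)) stop("invalid characters: ", paste(bad, collapse = ", "))
  sum(GC_WEIGHT[names(counts)] * as.numeric(counts)) / nchar(s)
}

#' Maximal repeated pairs
#'
#' All maximal repeated pairs within one sequence of length >= \code{minLen}:
#' direct repeats and, when \code{includeRevcomp}, inverted repeats (the
#' second copy is the reverse complement of the first). Maximality means the
#' matched pair can be extended in neither direction; the trivial
#' whole-sequence self pair is excluded. Output ordering is deterministic.
#'
#' @param seq DNA sequence
#' @param minLen minimum repeat length (default 20)
#' @param includeRevcomp also report inverted pairs (default TRUE)
#' @return data.frame (1-based): start1, start2, length, orientation
#' @export
findMaximalRepeats <- function(seq, minLen = 20L, includeRevcomp = TRUE) {
  s <- .asChar(seq)
  if (nchar(s) < minLen) stop("sequence shorter than minLen")
  df <- cpp_maximal_repeats(s, as.integer(minLen), includeRevcomp)
  out <- data.frame(start1 = df$start1 + 1L, start2 = df$start2 + 1L,
                    length = df$length,
                    orientation = c("direct", "inverted")[df$inverted + 1L],
                    stringsAsFactors = FALSE)
  out <- out[order(out$start1, out$start2, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect the plastome inverted repeat
#'
#' Returns the longest inverted maximal repeat pair of length >=
#' \code{minLen} as an \code{IRanges} of length two named IRa/IRb, or
#' \code{NULL} when no such pair exists.
#'
#' @param seq DNA sequence
#' @param minLen minimum IR length considered (default 1000)
#' @return \code{IRanges} (IRa, IRb) or \code{NULL}
#' @export
detectInvertedRepeat <- function(seq, minLen = 1000L) {
  s <- .asChar(seq)
  if (nchar(s) < 2 * minLen) return(NULL)
  reps <- findMaximalRepeats(s, minLen = minLen, includeRevcomp = TRUE)
  reps <- reps[reps$orientation == "inverted", , drop = FALSE]
  if (nrow(reps) == 0) return(NULL)
  reps <- reps[order(-reps$length, reps$start1), , drop = FALSE]
  top <- reps[1, ]
  IRanges::IRanges(start = c(top$start1, top$start2), width = top$length,
                   names = c("IRa", "IRb"))
}

#' Non-IR repeat content
#'
#' Detects the inverted repeat, enumerates all maximal repeats of length >=
#' \code{minLen}, discards pairs whose copies both lie inside the IR copies,
#' and sums the remaining repeat-covered bases. The default \code{"union"}
#' mode counts each covered base once; \code{"pairs"} sums both copy lengths
#' per pair.
#'
#' @param seq DNA sequence
#' @param minLen minimum repeat length (default 20)
#' @param sumMode "union" (default) or "pairs"
#' @param irMinLen minimum IR length for exclusion (default 1000)
#' @return total repeat bases (bp)
#' @export
repeatContent <- function(seq, minLen = 20L, sumMode = c("union", "pairs"),
                          irMinLen = 1000L) {
  sumMode <- match.arg(sumMode)
  s <- .asChar(seq)
  if (nchar(s) < minLen) return(0L)
  ir <- detectInvertedRepeat(s, minLen = irMinLen)
  reps <- findMaximalRepeats(s, minLen = minLen, includeRevcomp = TRUE)
  if (nrow(reps) == 0) return(0L)
  if (!is.null(ir)) {
    insideIR <- function(st, len) {
      iv <- IRanges::IRanges(st, width = len)
      IRanges::overlapsAny(iv, ir, type = "within")
    }
    both <- insideIR(reps$start1, reps$length) &
      insideIR(reps$start2, reps$length)
    reps <- reps[!both, , drop = FALSE]
  }
  if (nrow(reps) == 0) return(0L)
  if (sumMode == "pairs") return(sum(2L * reps$length))
  iv <- IRanges::IRanges(c(reps$start1, reps$start2),
                         width = rep(reps$length, 2))
  sum(IRanges::width(IRanges::reduce(iv)))
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value (delegates to \code{stats::t.test}).
#'
#' @param x,y numeric samples (each n >= 2; at least one with nonzero
#'   variance)
#' @return one-row data.frame: n_x, n_y, mean_x, mean_y, t, df, p
#' @export
welchTTest <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per group")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) != mean(y)) stop("degenerate input: zero variance in both groups")
    return(data.frame(n_x = length(x), n_y = length(y), mean_x = mean(x),
                      mean_y = mean(y), t = 0, df = length(x) + length(y) - 2,
                      p = 1))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  data.frame(n_x = length(x), n_y = length(y), mean_x = mean(x),
             mean_y = mean(y), t = unname(tt$statistic),
             df = unname(tt$parameter), p = tt$p.value)
}

#' Compare parameters between good and poor assemblies
#'
#' One Welch t-test per parameter column between the good- and poor-labelled
#' samples. No multiple-testing correction is applied by default (mirroring a
#' per-parameter presentation); \code{holm = TRUE} adds a Holm-adjusted
#' column.
#'
#' @param table per-sample data.frame with a label column and numeric
#'   parameter columns
#' @param parameters character vector of parameter column names
#' @param labelCol name of the label column (values "good"/"poor")
#' @param holm add Holm-corrected p-values
#' @return data.frame: parameter, n_good, n_poor, mean_good, mean_poor, t,
#'   df, p (and p_holm when requested)
#' @export
compareGoodPoor <- function(table, parameters, labelCol = "label",
                            holm = FALSE) {
  if (!labelCol %in% names(table)) stop("missing column '", labelCol, "'")
  miss <- setdiff(parameters, names(table))
  if (length(miss)) stop("missing column '", miss[1], "'")
  good <- table[table[[labelCol]] == "good", , drop = FALSE]
  poor <- table[table[[labelCol]] == "poor", , drop = FALSE]
  if (nrow(good) < 2 || nrow(poor) < 2)
    stop("need at least 2 samples per label")
  rows <- lapply(parameters, function(p) {
    w <- welchTTest(good[[p]], poor[[p]])
    data.frame(parameter = p, n_good = w$n_x, n_poor = w$n_y,
               mean_good = w$mean_x, mean_poor = w$mean_y, t = w$t, df = w$df,
               p = w$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (holm) out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out
}

#' Per-sample assembly QC report
#'
#' Ranks the assembly against the database by average common substring
#' distance, scores the length-ratio error against the top match, classifies
#' good/poor, and computes GC content, non-IR repeat content, the detected
#' inverted repeat, and (when reads are supplied) the median pseudo-mapping
#' depth.
#'
#' @param assembly draft sequence (\code{DNAString} or character)
#' @param db reference \code{DNAStringSet} (named by sample id)
#' @param taxonomy optional taxonomy data.frame (sample_id, genus, species)
#' @param reads optional read set for depth estimation
#' @param sampleId sample identifier
#' @param threshold good/poor error threshold (default 0.1)
#' @param irMinLen,repeatMinLen repeat detection parameters
#' @return an [AssemblyReport-class]
#' @export
assemblyReport <- function(assembly, db, taxonomy = NULL, reads = NULL,
                           sampleId = "sample", threshold = 0.1,
                           irMinLen = 1000L, repeatMinLen = 20L) {
  s <- .asChar(assembly)
  if (!nzchar(s)) {
    return(new("AssemblyReport", sampleId = sampleId, assemblyLength = 0,
               refMatchLength = NA_real_, refMatchId = NA_character_,
               error = NA_real_, label = "failed", gc = NA_real_,
               repeatContent = NA_real_, ir = IRanges::IRanges(),
               depthMedian = NA_real_))
  }
  ranking <- rankDatabase(s, db, taxonomy = taxonomy, queryId = sampleId)
  top <- hits(ranking)[1, ]
  refLen <- Biostrings::width(db)[match(top$subject_id, names(db))]
  err <- assemblyError(nchar(s), refLen)
  ir <- detectInvertedRepeat(s, minLen = irMinLen)
  depthMed <- if (is.null(reads)) NA_real_ else
    estimateDepth(.readPool(reads), s)$median
  new("AssemblyReport", sampleId = sampleId, assemblyLength = nchar(s),
      refMatchLength = as.numeric(refLen), refMatchId = top$subject_id,
      error = err, label = classifyAssembly(err, threshold), gc = gcContent(s),
      repeatContent = as.numeric(repeatContent(s, minLen = repeatMinLen,
                                               irMinLen = irMinLen)),
      ir = if (is.null(ir)) IRanges::IRanges() else ir,
      depthMedian = depthMed)
}
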