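IUPAC_DNA <- "ACGTRYSWKMBDHVN"

# Upper-case, map U->T, and reject anything outside the IUPAC DNA alphabet.
.sanitizeChars <- function(x, ids = NULL) {
  x <- chartr("u", "t", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grep(sprintf("[^%s]", IUPAC_DNA), x)
  if (length(bad)) {
    id <- if (!is.null(ids)) ids[bad[1]] else as.character(bad[1])
    ch <- regmatches(x[bad[1]],
                     regexpr(sprintf("[^%s]", IUPAC_DNA), x[bad[1]]))
    stop("record '", id, "' contains non-IUPAC character '", ch, "'")
  }
  x
}

.guessFormat <- function(path) {
  p <- sub("\\.(gz|bgz)$", "", path, ignore.case = TRUE)
  if (grepl("\\.(fq|fastq)$", p, ignore.case = TRUE)) "fastq" else "fasta"
}

# Names the offending record when a FASTQ file is structurally malformed.
.diagnoseFastq <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n <- length(lines)
  if (n %% 4 != 0)
    stop("FASTQ parse error in '", path, "': ", n,
         " lines is not a multiple of 4")
  for (i in seq_len(n / 4)) {
    b <- (i - 1) * 4
    id <- sub("^@", "", strsplit(lines[b + 1], "[ \t]")[[1]][1])
    if (!startsWith(lines[b + 1], "@") || !startsWith(lines[b + 3], "+"))
      stop("FASTQ parse error at record ", i, " ('", id, "'), line ", b + 1,
           ": missing @/+ markers")
    if (nchar(lines[b + 2]) != nchar(lines[b + 4]))
      stop("FASTQ parse error at record ", i, " ('", id, "'), line ", b + 4,
           ": quality length ", nchar(lines[b + 4]),
           " differs from sequence length ", nchar(lines[b + 2]))
  }
  invisible(TRUE)
}

#' Read sequences from FASTA or FASTQ
#'
#' Reads a (possibly gzip-compressed) FASTA or FASTQ file into a
#' \code{DNAStringSet} (FASTA) or \code{QualityScaledDNAStringSet} (FASTQ,
#' Phred+33). Input is sanitised: lower case is upper-cased, \code{U} is
#' mapped to \code{T}, and characters outside the IUPAC DNA alphabet
#' (\code{ACGTRYSWKMBDHVN}) raise an error naming the record. Records are
#' returned in file order; names hold the full header (id and description).
#'
#' @param path file path
#' @param format "auto" (by extension), "fasta" or "fastq"
#' @return \code{DNAStringSet} or \code{QualityScaledDNAStringSet}
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT"), fa)
#' readSequences(fa)
#' @export
readSequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: '", path, "'")
  if (format == "auto") format <- .guessFormat(path)
  if (format == "fasta") {
    raw <- Biostrings::readBStringSet(path)
    seqs <- .sanitizeChars(as.character(raw), names(raw))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- names(raw)
    return(out)
  }
  parsed <- tryCatch({
    raw <- Biostrings::readBStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    list(seqs = as.character(raw),
         quals = as.character(S4Vectors::mcols(raw)$qualities),
         ids = names(raw))
  }, error = function(e) {
    .diagnoseFastq(path)  # stops with a named record if malformed
    stop(conditionMessage(e))
  })
  seqs <- parsed$seqs
  quals <- parsed$quals
  mism <- which(nchar(seqs) != nchar(quals))
  if (length(mism))
    stop("FASTQ parse error at record ", mism[1], " ('", parsed$ids[mism[1]],
         "'): sequence and quality lengths differ")
  raw <- stats::setNames(Biostrings::BStringSet(seqs), parsed$ids)
  seqs <- .sanitizeChars(seqs, names(raw))
  out <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
  names(out) <- names(raw)
  out
}

#' Write sequences to FASTA or FASTQ
#'
#' Round-trips with [readSequences()]. Writing FASTQ requires quality scores
#' (a \code{QualityScaledDNAStringSet}); a \code{.gz} suffix triggers gzip
#' compression.
#'
#' @param x \code{DNAStringSet} or \code{QualityScaledDNAStringSet}
#' @param path output path
#' @param format "auto" (by extension), "fasta" or "fastq"
#' @param lineWidth FASTA line width (default 60)
#' @return invisibly, \code{path}
#' @export
writeSequences <- function(x, path, format = c("auto", "fasta", "fastq"),
                           lineWidth = 60L) {
  format <- match.arg(format)
  if (format == "auto") format <- .guessFormat(path)
  compress <- grepl("\\.gz$", path, ignore.case = TRUE)
  if (format == "fastq") {
    if (!is(x, "QualityScaledXStringSet"))
      stop("records without quality scores cannot be written as FASTQ")
    Biostrings::writeQualityScaledXStringSet(x, path, compress = compress)
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta", width = lineWidth,
                                compress = compress)
  }
  invisible(path)
}

#' @describeIn readSequences IUPAC-aware reverse complement of plain
#'   character vectors (degenerate codes map to their complements:
#'   R<->Y, S<->S, W<->W, K<->M, B<->V, D<->H, N<->N). An involution.
#' @param x character vector of IUPAC DNA strings
#' @param ... unused
#' @export
setMethod("reverseComplement", "character", function(x, ...) {
  x <- .sanitizeChars(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
})
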