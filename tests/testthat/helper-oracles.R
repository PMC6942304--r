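# Independent brute-force oracles for the exact-match machinery, built on a
# longest-common-extension (LCE) table. Ambiguity codes match nothing, as in
# the package's exact-match semantics.

ACGT <- c("A", "C", "G", "T")

randomDNA <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(ACGT, n, replace = TRUE, prob = p), collapse = "")
}

randomIupac <- function(n, ambProb = 0.05) {
  amb <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
  pool <- c(rep(ACGT, each = 20), amb)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

rcChar <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(x)))

# L[i, j] = length of the longest common extension of a[i:] and b[j:]
lceMatrix <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  L <- matrix(0L, n + 1L, m + 1L)
  for (i in n:1) {
    hit <- (A[i] == B) & (A[i] %in% ACGT)
    L[i, 1:m] <- ifelse(hit, L[i + 1L, 2:(m + 1L)] + 1L, 0L)
  }
  L[seq_len(n), seq_len(m), drop = FALSE]
}

bruteMS <- function(q, s, bothStrands = TRUE) {
  ms <- apply(lceMatrix(q, s), 1, max)
  if (bothStrands) ms <- pmax(ms, apply(lceMatrix(q, rcChar(s)), 1, max))
  as.integer(ms)
}

# all left-maximal (hence maximal) matches of length >= minLen, one strand
bruteMemsOne <- function(q, s, minLen) {
  L <- lceMatrix(q, s)
  A <- strsplit(q, "")[[1]]
  B <- strsplit(s, "")[[1]]
  eq <- function(x, y) x == y && x %in% ACGT
  out <- list()
  for (i in seq_len(nrow(L))) for (j in seq_len(ncol(L))) {
    if (L[i, j] < minLen) next
    if (i > 1 && j > 1 && eq(A[i - 1], B[j - 1])) next
    out[[length(out) + 1L]] <- c(i, j, L[i, j])
  }
  if (!length(out)) return(matrix(integer(0), 0, 3))
  do.call(rbind, out)
}

bruteMEMs <- function(q, s, minLen) {
  plus <- bruteMemsOne(q, s, minLen)
  rows <- list()
  if (nrow(plus))
    rows$p <- data.frame(q_start = plus[, 1], s_start = plus[, 2],
                         length = plus[, 3], strand = "+")
  minus <- bruteMemsOne(q, rcChar(s), minLen)
  if (nrow(minus))
    rows$m <- data.frame(q_start = minus[, 1],
                         s_start = nchar(s) - minus[, 2] - minus[, 3] + 2L,
                         length = minus[, 3], strand = "-")
  if (!length(rows))
    return(data.frame(q_start = integer(0), s_start = integer(0),
                      length = integer(0), strand = character(0)))
  df <- do.call(rbind, rows)
  df <- df[order(df$q_start, df$s_start, df$strand, df$length), , drop = FALSE]
  rownames(df) <- NULL
  df
}

bruteMaxRepeats <- function(s, minLen, includeRevcomp = TRUE) {
  rows <- list()
  direct <- bruteMemsOne(s, s, minLen)
  if (nrow(direct)) {
    keep <- direct[, 1] < direct[, 2]
    if (any(keep))
      rows$d <- data.frame(start1 = direct[keep, 1], start2 = direct[keep, 2],
                           length = direct[keep, 3], orientation = "direct")
  }
  if (includeRevcomp) {
    inv <- bruteMemsOne(s, rcChar(s), minLen)
    if (nrow(inv)) {
      a <- inv[, 1]
      b <- nchar(s) - inv[, 2] - inv[, 3] + 2L
      s1 <- pmin(a, b); s2 <- pmax(a, b)
      keep <- a != b
      if (any(keep)) {
        df <- unique(data.frame(start1 = s1[keep], start2 = s2[keep],
                                length = inv[keep, 3],
                                orientation = "inverted"))
        rows$i <- df
      }
    }
  }
  if (!length(rows))
    return(data.frame(start1 = integer(0), start2 = integer(0),
                      length = integer(0), orientation = character(0)))
  df <- do.call(rbind, rows)
  df <- df[order(df$start1, df$start2, df$length), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# closed-form Welch t-test, independent of stats::t.test
bruteWelch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# exhaustive optimal colinear chain score over <= ~12 anchors (0-based inputs)
bruteBestChain <- function(q0, s0, len, maxGap) {
  n <- length(q0)
  best <- 0
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (!length(idx)) next
    idx <- idx[order(q0[idx], s0[idx])]
    ok <- TRUE
    if (length(idx) > 1) {
      for (k in 2:length(idx)) {
        i <- idx[k]; j <- idx[k - 1]
        gq <- q0[i] - (q0[j] + len[j])
        gs <- s0[i] - (s0[j] + len[j])
        if (gq < 0 || gs < 0 || gq > maxGap || gs > maxGap) { ok <- FALSE; break }
      }
    }
    if (ok) best <- max(best, sum(len[idx]))
  }
  best
}

# adapter-trim oracle: scan every placement, score by matching bases
bruteTrim <- function(read, adapter, minOverlap = 3, maxErrorRate = 0.1) {
  r <- strsplit(read, "")[[1]]
  a <- strsplit(adapter, "")[[1]]
  bestScore <- -1; bestP <- length(r)
  for (p in seq_len(length(r) - minOverlap + 1)) {
    L <- min(length(a), length(r) - p + 1)
    if (L < minOverlap) break
    mm <- sum(r[p:(p + L - 1)] != a[1:L] |
                !(r[p:(p + L - 1)] %in% ACGT))
    if (mm > floor(maxErrorRate * L)) next
    score <- L - mm
    if (score > bestScore) { bestScore <- score; bestP <- p - 1 }
  }
  substr(read, 1, bestP)
}

# order check that tolerates repeat-induced placement ties: TRUE if some
# assignment of occurrence positions (either orientation) is non-decreasing
orderConsistent <- function(contigSeqs, genome) {
  prev <- -Inf
  for (cs in contigSeqs) {
    occ <- c(unlist(gregexpr(cs, genome, fixed = TRUE)),
             unlist(gregexpr(rcChar(cs), genome, fixed = TRUE)))
    occ <- sort(occ[occ > 0])
    nxt <- occ[occ >= prev]
    if (!length(nxt)) return(FALSE)
    prev <- nxt[1]
  }
  TRUE
}
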