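# Brute-force oracles: enumerate every window and recompute with plain loops,
# independently of the vectorized search code they are used to check.

rand_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

revcomp_rna <- function(s) {
  paste(rev(chartr("ACGU", "UGCA",
                   strsplit(s, "", fixed = TRUE)[[1L]])), collapse = "")
}

hamming_chr <- function(a, b) {
  ca <- strsplit(a, "")[[1L]]; cb <- strsplit(b, "")[[1L]]
  sum(ca != cb)
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"), B = c("C", "G", "U"),
  D = c("A", "G", "U"), H = c("A", "C", "U"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "U"))

# every window of each sequence (and optionally its reverse complement),
# with forward-strand coordinates
enumerate_windows <- function(seqs, k, bothStrands = FALSE) {
  out <- list()
  for (id in names(seqs)) {
    L <- nchar(seqs[[id]])
    strands <- if (bothStrands) c("+", "-") else "+"
    for (st in strands) {
      s <- if (st == "+") seqs[[id]] else revcomp_rna(seqs[[id]])
      if (L < k) next
      i <- seq_len(L - k + 1L)
      fs <- if (st == "+") i else L - (i + k - 1L) + 1L
      out[[length(out) + 1L]] <-
        data.frame(seq_id = id, start = fs, end = fs + k - 1L, strand = st,
                   window = substring(s, i, i + k - 1L),
                   stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      window = character(0)))
  do.call(rbind, out)
}

oracle_near_matches <- function(site, seqs, maxDiff, bothStrands = FALSE) {
  wins <- enumerate_windows(seqs, nchar(site), bothStrands)
  wins$mismatches <- vapply(wins$window, hamming_chr, numeric(1L), b = site)
  wins <- wins[wins$mismatches <= maxDiff, , drop = FALSE]
  wins[order(wins$mismatches, wins$seq_id, wins$start), , drop = FALSE]
}

oracle_iupac <- function(pattern, seqs, maxMismatch, bothStrands = FALSE) {
  pat <- strsplit(pattern, "")[[1L]]
  wins <- enumerate_windows(seqs, length(pat), bothStrands)
  wins$mismatches <- vapply(wins$window, function(w) {
    cw <- strsplit(w, "")[[1L]]
    sum(vapply(seq_along(pat),
               function(j) !(cw[j] %in% IUPAC_SETS[[pat[j]]]), logical(1L)))
  }, numeric(1L))
  wins <- wins[wins$mismatches <= maxMismatch, , drop = FALSE]
  wins[order(wins$mismatches, wins$seq_id, wins$start), , drop = FALSE]
}

oracle_scan <- function(array, seqs, table, minScore, bothStrands = FALSE) {
  m <- motifs(array)
  wins <- enumerate_windows(seqs, nrow(m), bothStrands)
  wgt <- c(PERFECT = 1, PARTIAL = 0.5, MISMATCH = 0)
  wins$score <- vapply(wins$window, function(w) {
    cw <- strsplit(w, "")[[1L]]
    sum(vapply(seq_len(nrow(m)), function(j)
      wgt[[classifyMatch(c(m$res5[j], m$res35[j]), cw[j], table)]],
      numeric(1L)))
  }, numeric(1L))
  wins <- wins[wins$score >= minScore, , drop = FALSE]
  wins[order(-wins$score, wins$seq_id, wins$start), , drop = FALSE]
}

# random PPR array over the canonical code pairs
CANONICAL_PAIRS <- list(c("T", "N"), c("T", "D"), c("N", "D"),
                        c("N", "N"), c("S", "N"), c("S", "D"))

rand_array <- function(n, name = "rand") {
  picks <- sample(length(CANONICAL_PAIRS), n, replace = TRUE)
  pprArray(name,
           vapply(picks, function(i) CANONICAL_PAIRS[[i]][1L], character(1L)),
           vapply(picks, function(i) CANONICAL_PAIRS[[i]][2L], character(1L)))
}

expect_same_hits <- function(hits, oracle, metric) {
  hits <- as.data.frame(hits)
  expect_equal(nrow(hits), nrow(oracle))
  if (nrow(hits) > 0L) {
    rownames(hits) <- rownames(oracle) <- NULL
    expect_equal(hits[, c("seq_id", "start", "end", "strand")],
                 oracle[, c("seq_id", "start", "end", "strand")])
    expect_equal(hits[[metric]], oracle[[metric]])
  }
}
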