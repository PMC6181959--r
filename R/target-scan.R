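# Binding-site searches: Hamming search for a literal site, degenerate IUPAC
# pattern search, PPR-array sliding-window scoring, and construction of an
# off-target audit pattern from a design target plus natural targets.

#' Degenerate IUPAC pattern with per-position provenance
#'
#' @slot pattern IUPAC string (RNA alphabet).
#' @slot provenance `data.frame` recording, per position, the design base,
#'   the observed bases and the rule that produced the emitted symbol.
#' @seealso [buildOfftargetPattern()], [iupacSearch()]
#' @export
setClass("DegeneratePattern",
  representation(pattern = "character", provenance = "data.frame"))

setValidity("DegeneratePattern", function(object) {
  if (nchar(object@pattern) == 0L) return("pattern must be non-empty")
  sym <- strsplit(object@pattern, "", fixed = TRUE)[[1L]]
  bad <- setdiff(sym, names(IUPAC_RNA))
  if (length(bad) > 0L)
    return(paste("invalid IUPAC symbol(s):", paste(unique(bad), collapse = ", ")))
  TRUE
})

setMethod("show", "DegeneratePattern", function(object) {
  cat("DegeneratePattern ", object@pattern, "\n", sep = "")
  if (nrow(object@provenance) > 0L) {
    deg <- object@provenance[object@provenance$rule != "unanimous", ]
    if (nrow(deg) > 0L)
      cat("  degenerate positions:",
          paste0(deg$pos, ":", deg$symbol, collapse = " "), "\n")
  }
})

# normalize sequence input (XStringSet or named character) to a named
# character vector of RNA strings
#' @keywords internal
#' @noRd
.seqsAsRNA <- function(seqs) {
  if (is(seqs, "XStringSet")) {
    out <- .asRNA(as.character(seqs))
    names(out) <- names(seqs)
  } else {
    out <- .asRNA(seqs)
    names(out) <- if (is.null(names(seqs))) paste0("seq", seq_along(out))
                  else names(seqs)
  }
  out
}

#' Count differences between two equal-length sequences
#'
#' Hamming distance over aligned positions, case-insensitive, with T and U
#' equivalent. With `cuLenient = TRUE` a C/U difference counts half a
#' mismatch (the distinction PPR motifs make least well).
#'
#' @param a,b equal-length sequences.
#' @param cuLenient logical; count C<->U differences as 0.5.
#' @return number of differing positions.
#' @examples
#' countDifferences("ACGU", "ACGA")
#' @export
countDifferences <- function(a, b, cuLenient = FALSE) {
  ca <- .splitRNA(a); cb <- .splitRNA(b)
  if (length(ca) != length(cb))
    stop("sequences have unequal lengths (", length(ca), " vs ", length(cb),
         ")", call. = FALSE)
  diff <- ca != cb
  if (!cuLenient) return(sum(diff))
  cu <- diff & ((ca == "C" & cb == "U") | (ca == "U" & cb == "C"))
  sum(diff & !cu) + 0.5 * sum(cu)
}

#' @keywords internal
#' @noRd
.emptyHits <- function(metric = c("mismatches", "score")) {
  metric <- match.arg(metric)
  d <- S4Vectors::DataFrame(seq_id = character(0), start = integer(0),
                            end = integer(0), strand = character(0),
                            window = character(0))
  d[[metric]] <- numeric(0)
  d
}

# per-window mismatch counts of a literal site over one encoded sequence
#' @keywords internal
#' @noRd
.windowDiffCounts <- function(enc, site, cuLenient = FALSE) {
  k <- length(site)
  nw <- length(enc) - k + 1L
  if (nw < 1L) return(numeric(0))
  counts <- numeric(nw)
  for (j in seq_len(k)) {
    idx <- enc[j:(j + nw - 1L)]
    neq <- idx != site[j]
    neq[is.na(idx)] <- TRUE
    if (cuLenient) {
      cu <- (idx == 2L & site[j] == 4L) | (idx == 4L & site[j] == 2L)
      cu[is.na(cu)] <- FALSE
      counts <- counts + ifelse(cu, 0.5, as.numeric(neq))
    } else {
      counts <- counts + neq
    }
  }
  counts
}

#' Mismatch-tolerant search for a literal site
#'
#' Reports every window whose Hamming distance to `site` is at most
#' `maxDiff`, on the sense strand (and optionally the reverse complement).
#' Overlapping windows are all reported; hits are sorted by
#' (mismatches, seq_id, start).
#'
#' @param site the site sequence (RNA or DNA spelling).
#' @param seqs sequences to search: an `XStringSet` or a (named) character
#'   vector.
#' @param maxDiff maximum number of differences (>= 0). With
#'   `cuLenient = TRUE` C/U differences count 0.5 and the threshold applies
#'   to the rounded-up total.
#' @param bothStrands also search the reverse complement (genome-style
#'   scans); minus-strand hits report forward-strand coordinates.
#' @param cuLenient logical, see [countDifferences()].
#' @return `DataFrame` with columns `seq_id`, `start`, `end`, `strand`,
#'   `window` (the matched window, hit orientation) and `mismatches`.
#' @export
findNearMatches <- function(site, seqs, maxDiff, bothStrands = FALSE,
                            cuLenient = FALSE) {
  site <- .asRNA(site)
  if (nchar(site) == 0L) stop("site must be non-empty", call. = FALSE)
  if (maxDiff < 0) stop("maxDiff must be >= 0", call. = FALSE)
  siteEnc <- match(.splitRNA(site), RNA_BASES)
  if (anyNA(siteEnc)) stop("site contains non-ACGU characters", call. = FALSE)
  seqs <- .seqsAsRNA(seqs)

  res <- list()
  for (id in names(seqs)) {
    strands <- if (bothStrands) c("+", "-") else "+"
    L <- nchar(seqs[[id]])
    for (st in strands) {
      s <- if (st == "+") seqs[[id]] else .revCompRNA(seqs[[id]])
      enc <- match(strsplit(s, "", fixed = TRUE)[[1L]], RNA_BASES)
      counts <- .windowDiffCounts(enc, siteEnc, cuLenient)
      keep <- which(ceiling(counts) <= maxDiff)
      if (length(keep) == 0L) next
      start <- keep; end <- keep + length(siteEnc) - 1L
      if (st == "-") {
        fstart <- L - end + 1L; fend <- L - start + 1L
      } else {
        fstart <- start; fend <- end
      }
      res[[length(res) + 1L]] <- S4Vectors::DataFrame(
        seq_id = id, start = as.integer(fstart), end = as.integer(fend),
        strand = st,
        window = substring(s, start, end),
        mismatches = counts[keep])
    }
  }
  if (length(res) == 0L) return(.emptyHits("mismatches"))
  hits <- do.call(rbind, res)
  hits[order(hits$mismatches, hits$seq_id, hits$start), , drop = FALSE]
}

#' Search sequences with a degenerate IUPAC pattern
#'
#' A window position matches when its base belongs to the pattern symbol's
#' base class (`N` matches everything, `R` = A/G, `Y` = C/U, and the full
#' IUPAC set is supported). Windows failing at most `maxMismatch` positions
#' are reported, sorted by (mismatches, seq_id, start).
#'
#' @param pattern an IUPAC string or a [DegeneratePattern-class].
#' @param seqs sequences to search (as in [findNearMatches()]).
#' @param maxMismatch maximum number of failing positions (>= 0).
#' @param bothStrands also search the reverse complement.
#' @return `DataFrame` of hits with a `mismatches` column.
#' @examples
#' iupacSearch("RY", c(x = "GACU"), maxMismatch = 0)
#' @export
iupacSearch <- function(pattern, seqs, maxMismatch = 0, bothStrands = FALSE) {
  if (is(pattern, "DegeneratePattern")) pattern <- pattern@pattern
  pattern <- .asRNA(pattern)
  sym <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  bad <- setdiff(sym, names(IUPAC_RNA))
  if (length(bad) > 0L || length(sym) == 0L)
    stop("invalid IUPAC symbol(s) in pattern: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  if (maxMismatch < 0) stop("maxMismatch must be >= 0", call. = FALSE)
  # allowed[b, j] == TRUE when base b satisfies pattern position j
  allowed <- vapply(sym, function(s) RNA_BASES %in% IUPAC_RNA[[s]],
                    logical(4L))
  seqs <- .seqsAsRNA(seqs)

  res <- list()
  for (id in names(seqs)) {
    strands <- if (bothStrands) c("+", "-") else "+"
    L <- nchar(seqs[[id]])
    for (st in strands) {
      s <- if (st == "+") seqs[[id]] else .revCompRNA(seqs[[id]])
      enc <- match(strsplit(s, "", fixed = TRUE)[[1L]], RNA_BASES)
      nw <- length(enc) - length(sym) + 1L
      if (nw < 1L) next
      counts <- numeric(nw)
      for (j in seq_along(sym)) {
        idx <- enc[j:(j + nw - 1L)]
        ok <- allowed[idx, j]
        ok[is.na(idx)] <- (sym[j] == "N")   # subject N satisfies only pattern N
        counts <- counts + !ok
      }
      keep <- which(counts <= maxMismatch)
      if (length(keep) == 0L) next
      start <- keep; end <- keep + length(sym) - 1L
      if (st == "-") {
        fstart <- L - end + 1L; fend <- L - start + 1L
      } else {
        fstart <- start; fend <- end
      }
      res[[length(res) + 1L]] <- S4Vectors::DataFrame(
        seq_id = id, start = as.integer(fstart), end = as.integer(fend),
        strand = st, window = substring(s, start, end),
        mismatches = counts[keep])
    }
  }
  if (length(res) == 0L) return(.emptyHits("mismatches"))
  hits <- do.call(rbind, res)
  hits[order(hits$mismatches, hits$seq_id, hits$start), , drop = FALSE]
}

#' Build a degenerate off-target audit pattern
#'
#' Generalizes a design target using the variation seen across the parent
#' protein's natural targets. Per position: if every natural target carries
#' the design base, the base itself is emitted; if the observed bases all
#' fall within one purine (R) or pyrimidine (Y) class containing the design
#' base, that class symbol is emitted; otherwise N. The resulting pattern
#' never excludes a natural target at positions whose bases drove the
#' degeneracy.
#'
#' @param designTarget the designed binding site (RNA string).
#' @param naturalTargets character vector of equal-length natural sites.
#' @return a [DegeneratePattern-class] with per-position provenance.
#' @export
buildOfftargetPattern <- function(designTarget, naturalTargets) {
  d <- .splitRNA(designTarget)
  nat <- lapply(naturalTargets, .splitRNA)
  if (any(vapply(nat, length, integer(1L)) != length(d)))
    stop("natural targets must have the same length as the design target",
         call. = FALSE)
  .checkBases(d)
  lapply(nat, .checkBases)
  purine <- c("A", "G"); pyrimidine <- c("C", "U")
  rows <- lapply(seq_along(d), function(i) {
    obs <- unique(c(d[i], vapply(nat, `[`, character(1L), i)))
    if (length(obs) == 1L) {
      list(symbol = d[i], rule = "unanimous")
    } else if (all(obs %in% purine)) {
      list(symbol = "R", rule = "purine-class")
    } else if (all(obs %in% pyrimidine)) {
      list(symbol = "Y", rule = "pyrimidine-class")
    } else {
      list(symbol = "N", rule = "class-conflict")
    }
  })
  prov <- data.frame(
    pos = seq_along(d),
    design = d,
    observed = vapply(seq_along(d), function(i)
      paste(sort(unique(c(d[i], vapply(nat, `[`, character(1L), i)))),
            collapse = ""), character(1L)),
    rule = vapply(rows, `[[`, character(1L), "rule"),
    symbol = vapply(rows, `[[`, character(1L), "symbol"),
    stringsAsFactors = FALSE)
  new("DegeneratePattern",
      pattern = paste(prov$symbol, collapse = ""), provenance = prov)
}

#' Sliding-window scan of a PPR array over sequences
#'
#' Scores every window of length `length(array)` with [scoreAlignment()]'s
#' weight model and reports windows reaching `minScore`. Transcript scans
#' cover the sense strand only; genome scans cover both strands
#' (`bothStrands = TRUE`), with minus-strand hits reported in forward-strand
#' coordinates. Hits are ranked by descending score, ties by
#' (seq_id, start).
#'
#' @param array a [PPRArray-class].
#' @param seqs sequences to scan (as in [findNearMatches()]).
#' @param table a [CodeTable-class].
#' @param minScore minimum score to report (>= 0).
#' @param bothStrands scan both strands (use for genome sequences).
#' @return `DataFrame` of hits with a `score` column.
#' @export
scanArray <- function(array, seqs, table, minScore, bothStrands = FALSE) {
  stopifnot(is(array, "PPRArray"))
  if (minScore < 0) stop("minScore must be >= 0", call. = FALSE)
  w <- .weightMatrix(array, table)
  n <- ncol(w)
  seqs <- .seqsAsRNA(seqs)

  res <- list()
  for (id in names(seqs)) {
    strands <- if (bothStrands) c("+", "-") else "+"
    L <- nchar(seqs[[id]])
    for (st in strands) {
      s <- if (st == "+") seqs[[id]] else .revCompRNA(seqs[[id]])
      enc <- match(strsplit(s, "", fixed = TRUE)[[1L]], RNA_BASES)
      nw <- length(enc) - n + 1L
      if (nw < 1L) next
      sc <- numeric(nw)
      for (j in seq_len(n)) {
        wj <- w[, j]
        v <- wj[enc[j:(j + nw - 1L)]]
        v[is.na(v)] <- 0
        sc <- sc + v
      }
      keep <- which(sc >= minScore)
      if (length(keep) == 0L) next
      start <- keep; end <- keep + n - 1L
      if (st == "-") {
        fstart <- L - end + 1L; fend <- L - start + 1L
      } else {
        fstart <- start; fend <- end
      }
      res[[length(res) + 1L]] <- S4Vectors::DataFrame(
        seq_id = id, start = as.integer(fstart), end = as.integer(fend),
        strand = st, window = substring(s, start, end),
        score = unname(sc[keep]))
    }
  }
  if (length(res) == 0L) return(.emptyHits("score"))
  hits <- do.call(rbind, res)
  hits[order(-hits$score, hits$seq_id, hits$start), , drop = FALSE]
}

#' Per-motif match classes for a scan hit
#'
#' Convenience wrapper recomputing the match-class vector for one hit row
#' returned by [scanArray()].
#'
#' @param array a [PPRArray-class].
#' @param hit a single hit row.
#' @param table a [CodeTable-class].
#' @return character vector of match classes.
#' @export
hitClasses <- function(array, hit, table) {
  scoreAlignment(array, hit$window[1L], table)@classes
}
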