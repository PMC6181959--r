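# Re-targeting a PPR array: choose specificity-residue edits that make every
# motif a predicted perfect match to a new RNA target, and emit the modified
# protein sequence.

# canonical preference order used to break ties between replacement pairs
CANONICAL_PAIR_ORDER <- c("T,N", "N,D", "T,D", "N,N", "S,N", "S,D")

#' @keywords internal
#' @noRd
.choosePair <- function(current, candidates) {
  cur <- strsplit(current, ",", fixed = TRUE)[[1L]]
  shared <- vapply(candidates, function(k) {
    p <- strsplit(k, ",", fixed = TRUE)[[1L]]
    sum(p == cur)
  }, integer(1L))
  rank <- match(candidates, CANONICAL_PAIR_ORDER)
  rank[is.na(rank)] <- length(CANONICAL_PAIR_ORDER) + 1L
  ord <- order(-shared, rank, candidates)
  candidates[ord[1L]]
}

#' Design specificity-residue edits toward a new target
#'
#' Produces the minimal edit set converting `parent` into an array predicted
#' to bind `newTarget` perfectly: a motif is edited only when its current
#' residue pair does not already classify the new target base as a perfect
#' match. With `keepPartial = TRUE`, motifs whose current pair is a partial
#' match to the target base are left untouched. When several pairs encode
#' the target base, the pair sharing more residues with the current pair is
#' preferred, ties broken by a fixed canonical order
#' ((T,N), (N,D), (T,D), (N,N), (S,N), (S,D)).
#'
#' @param parent the parent [PPRArray-class].
#' @param newTarget RNA string of length `length(parent)`.
#' @param table a [CodeTable-class].
#' @param keepPartial leave partial-match motifs unedited.
#' @param naturalTargets optional named character vector of the parent's
#'   natural target sites; the design report scores the modified array on
#'   each of them as well as on the new target.
#' @return a [DesignResult-class].
#' @examples
#' tbl <- loadCodeTable()
#' arr <- pprArray("toy", c("T", "T"), c("D", "N"))  # recognizes GA
#' designRetarget(arr, "AA", tbl)
#' @export
designRetarget <- function(parent, newTarget, table, keepPartial = FALSE,
                           naturalTargets = character(0)) {
  stopifnot(is(parent, "PPRArray"))
  bases <- .splitRNA(newTarget)
  .checkBases(bases, "target base")
  m <- parent@motifs
  if (length(bases) != nrow(m))
    stop("new target length (", length(bases),
         ") must equal motif count (", nrow(m), ")", call. = FALSE)

  # residue pairs encoding each base as primary
  byBase <- lapply(RNA_BASES, function(b) {
    names(table@entries)[vapply(table@entries,
                                function(e) b %in% e$primary, logical(1L))]
  })
  names(byBase) <- RNA_BASES
  unreachable <- which(vapply(bases, function(b) length(byBase[[b]]) == 0L,
                              logical(1L)))
  if (length(unreachable) > 0L)
    stop("no residue pair encodes the target base as primary at position(s) ",
         paste(unreachable, collapse = ", "), call. = FALSE)

  newm <- m
  edits <- list()
  for (i in seq_len(nrow(m))) {
    cls <- classifyMatch(list(res5 = m$res5[i], res35 = m$res35[i]),
                         bases[i], table)
    if (cls == "PERFECT") next
    if (cls == "PARTIAL" && keepPartial) next
    cur <- .pairKey(m$res5[i], m$res35[i])
    pick <- .choosePair(cur, byBase[[bases[i]]])
    res <- strsplit(pick, ",", fixed = TRUE)[[1L]]
    oldEntry <- codeEntry(m$res5[i], m$res35[i], table)
    edits[[length(edits) + 1L]] <- data.frame(
      motif_index = i,
      old_res5 = m$res5[i], old_res35 = m$res35[i],
      new_res5 = res[1L], new_res35 = res[2L],
      old_bases = paste(oldEntry$primary, collapse = ""),
      new_base = bases[i], stringsAsFactors = FALSE)
    newm$res5[i] <- res[1L]
    newm$res35[i] <- res[2L]
  }
  edits <- if (length(edits)) do.call(rbind, edits) else
    data.frame(motif_index = integer(0), old_res5 = character(0),
               old_res35 = character(0), new_res5 = character(0),
               new_res35 = character(0), old_bases = character(0),
               new_base = character(0), stringsAsFactors = FALSE)

  # the modified protein sequence no longer matches the parent's residues,
  # so the designed array carries no proteinSeq; use emitProtein() for it
  modified <- new("PPRArray", name = paste0(parent@name, "-redesign"),
                  motifs = newm, proteinSeq = NA_character_)

  targets <- c(list(new_target = newTarget), as.list(naturalTargets))
  report <- lapply(targets, function(t)
    scoreAlignment(modified, t, table)@classes)
  new("DesignResult", array = modified, edits = edits, report = report)
}

setMethod("show", "DesignResult", function(object) {
  cat("DesignResult:", nrow(object@edits), "edit(s) on",
      length(object@array), "motifs\n")
  if (nrow(object@edits) > 0L) {
    with(object@edits, cat(paste0(
      "  motif ", motif_index, ": (", old_res5, ",", old_res35, ") -> (",
      new_res5, ",", new_res35, ") for base ", new_base, "\n"), sep = ""))
  }
  for (nm in names(object@report)) {
    cls <- object@report[[nm]]
    cat("  on ", nm, ": ", sum(cls == "PERFECT"), " perfect, ",
        sum(cls == "PARTIAL"), " partial, ",
        sum(cls == "MISMATCH"), " mismatch\n", sep = "")
  }
})

#' Accessors for design results
#'
#' @param design a [DesignResult-class].
#' @return `designEdits()` returns the edit table; `designedArray()` the
#'   modified [PPRArray-class]; `designReport()` the per-target match-class
#'   lists.
#' @export
designEdits <- function(design) design@edits

#' @rdname designEdits
#' @export
designedArray <- function(design) design@array

#' @rdname designEdits
#' @export
designReport <- function(design) design@report

#' Emit the modified protein sequence for a design
#'
#' Substitutes the residues at positions 5 and 35 of each edited motif
#' (relative to the motif's span in the parent protein) and leaves every
#' other residue unchanged; length is preserved. At most `2 * nrow(edits)`
#' residues change (fewer when one residue of a pair is already correct).
#'
#' @param parentProtein amino-acid string of the parent protein.
#' @param design a [DesignResult-class].
#' @return the modified amino-acid string.
#' @export
emitProtein <- function(parentProtein, design) {
  stopifnot(is(design, "DesignResult"))
  prot <- strsplit(toupper(parentProtein), "", fixed = TRUE)[[1L]]
  m <- design@array@motifs
  ed <- design@edits
  for (i in seq_len(nrow(ed))) {
    idx <- ed$motif_index[i]
    p5 <- m$span_start[idx] + 4L
    p35 <- m$span_start[idx] + 34L
    if (p35 > length(prot) || m$span_end[idx] > length(prot))
      stop("motif ", idx, " span exceeds protein length", call. = FALSE)
    prot[p5] <- ed$new_res5[i]
    prot[p35] <- ed$new_res35[i]
  }
  paste(prot, collapse = "")
}
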