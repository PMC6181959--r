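#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' PPR motif array
#'
#' An ordered array of P-class pentatricopeptide repeat (PPR) motifs, each
#' carrying the two specificity residues (positions 5 and 35 of the ~35-aa
#' motif) that determine which RNA base the motif prefers under the PPR code.
#' Motif 1 is the N-terminal motif and pairs with the 5'-most base of the
#' RNA target; each motif binds exactly one base.
#'
#' @slot name single identifier string.
#' @slot motifs `data.frame` with columns `index` (1-based, contiguous),
#'   `res5`, `res35` (one-letter amino acids, `X` = unknown), `span_start`,
#'   `span_end` (1-based inclusive residue coordinates in the parent protein).
#' @slot proteinSeq the full amino-acid sequence of the parent protein, or
#'   `NA_character_` when not supplied. When present, the residues at motif
#'   positions 5 and 35 must agree with `res5`/`res35`.
#'
#' @seealso [pprArray()], [readPPRArray()], [predictRecognition()]
#' @export
setClass("PPRArray",
  representation(name = "character", motifs = "data.frame",
                 proteinSeq = "character"),
  prototype(name = "array", proteinSeq = NA_character_))

setValidity("PPRArray", function(object) {
  m <- object@motifs
  msgs <- character(0)
  need <- c("index", "res5", "res35", "span_start", "span_end")
  if (!all(need %in% colnames(m)))
    return(paste("motifs must have columns", paste(need, collapse = ", ")))
  if (nrow(m) == 0L) msgs <- c(msgs, "array must contain at least one motif")
  if (nrow(m) > 0L && !identical(as.integer(m$index), seq_len(nrow(m))))
    msgs <- c(msgs, "motif indices must be 1..n in order, without gaps")
  badres <- setdiff(c(m$res5, m$res35), AA_ALPHABET1)
  if (length(badres) > 0L)
    msgs <- c(msgs, paste("invalid specificity residue(s):",
                          paste(unique(badres), collapse = ", ")))
  if (nrow(m) > 0L) {
    if (any(m$span_start < 1L) || any(m$span_end < m$span_start))
      msgs <- c(msgs, "motif spans must be non-empty with 1-based coordinates")
    if (nrow(m) > 1L) {
      o <- order(m$span_start)
      if (any(m$span_start[o][-1L] <= m$span_end[o][-nrow(m)]))
        msgs <- c(msgs, "motif spans must not overlap")
    }
  }
  if (!is.na(object@proteinSeq) && nrow(m) > 0L) {
    prot <- strsplit(object@proteinSeq, "", fixed = TRUE)[[1L]]
    if (max(m$span_end) > length(prot)) {
      msgs <- c(msgs, "motif spans exceed protein length")
    } else {
      p5 <- prot[m$span_start + 4L]
      p35 <- prot[m$span_start + 34L]
      ok <- (p5 == m$res5 | m$res5 == "X") & (p35 == m$res35 | m$res35 == "X")
      ok[m$span_end - m$span_start + 1L < 35L] <- FALSE
      if (!all(ok))
        msgs <- c(msgs, paste("protein residues at motif positions 5/35",
                              "disagree with res5/res35 for motif(s):",
                              paste(m$index[!ok], collapse = ", ")))
    }
  }
  if (length(msgs) == 0L) TRUE else msgs
})

#' PPR code table
#'
#' Maps a pair of specificity residues (position 5, position 35) to the RNA
#' bases that pair recognizes: a primary set (perfect match) and a secondary
#' set (partial match). Residue pairs absent from the table are handled by
#' `defaultPolicy`: `"partial-all"` treats all four bases as partial matches
#' (an uninformative motif never creates spurious mismatches) while
#' `"mismatch-all"` treats them all as mismatches.
#'
#' @slot entries named list; names are `"res5,res35"` pairs, values are lists
#'   with character elements `primary` and `secondary` (RNA bases).
#' @slot defaultPolicy `"partial-all"` or `"mismatch-all"`.
#'
#' @seealso [loadCodeTable()], [classifyMatch()]
#' @export
setClass("CodeTable",
  representation(entries = "list", defaultPolicy = "character"),
  prototype(defaultPolicy = "partial-all"))

setValidity("CodeTable", function(object) {
  msgs <- character(0)
  if (!object@defaultPolicy %in% c("partial-all", "mismatch-all"))
    msgs <- c(msgs, "defaultPolicy must be 'partial-all' or 'mismatch-all'")
  for (key in names(object@entries)) {
    e <- object@entries[[key]]
    res <- strsplit(key, ",", fixed = TRUE)[[1L]]
    if (length(res) != 2L || !all(res %in% AA_ALPHABET1)) {
      msgs <- c(msgs, paste0("malformed residue pair '", key, "'"))
      next
    }
    bad <- setdiff(c(e$primary, e$secondary), RNA_BASES)
    if (length(bad) > 0L)
      msgs <- c(msgs, paste0("entry (", key, "): invalid base(s) ",
                             paste(bad, collapse = ", ")))
    if (length(intersect(e$primary, e$secondary)) > 0L)
      msgs <- c(msgs, paste0("entry (", key,
                             "): primary and secondary sets overlap"))
  }
  if (length(msgs) == 0L) TRUE else msgs
})

#' Predicted recognition sequence of a PPR array
#'
#' Per-motif base preferences (primary = perfect, secondary = partial), in
#' 5' to 3' order of the RNA target (motif 1 first). Render to an IUPAC
#' string with [iupacString()].
#'
#' @slot primary list of character vectors, one per motif.
#' @slot secondary list of character vectors, one per motif.
#' @export
setClass("RecognitionSequence",
  representation(primary = "list", secondary = "list"))

setValidity("RecognitionSequence", function(object) {
  if (length(object@primary) != length(object@secondary))
    return("primary and secondary must have one entry per motif")
  TRUE
})

#' Scored placement of a PPR array on an RNA window
#'
#' @slot classes per-motif match classes (`"PERFECT"`, `"PARTIAL"`,
#'   `"MISMATCH"`).
#' @slot score sum of match weights (1.0 / 0.5 / 0.0).
#' @export
setClass("PPRAlignment",
  representation(classes = "character", score = "numeric"))

#' Result of re-targeting a PPR array
#'
#' @slot array the modified [PPRArray-class], differing from the parent only
#'   at the edited motifs' specificity residues.
#' @slot edits `data.frame` of the residue substitutions, one row per edited
#'   motif (columns `motif_index`, `old_res5`, `old_res35`, `new_res5`,
#'   `new_res35`, `old_bases`, `new_base`).
#' @slot report named list of per-motif match-class vectors: the modified
#'   array scored on the new target and on each parent natural target.
#' @export
setClass("DesignResult",
  representation(array = "PPRArray", edits = "data.frame", report = "list"))

#' Transcript model anchored on a genome
#'
#' Genomic anchor plus segment lengths of a mature transcript. `genomeStart`
#' is the genome coordinate of the transcript's 5'-most base (for minus-strand
#' transcripts this is the numerically largest coordinate of the span).
#'
#' @slot name transcript name.
#' @slot genomeId genome/sequence identifier.
#' @slot genomeStart 1-based genome coordinate of the transcript 5' end.
#' @slot strand `"+"` or `"-"`.
#' @slot utr5 5'-UTR length (nt).
#' @slot cds coding-sequence length (nt).
#' @slot utr3 3'-UTR length (nt); 0 is allowed (e.g. the Arabidopsis nad6
#'   mRNA ends at its last codon, with no stop codon or 3'-UTR).
#' @export
setClass("TranscriptModel",
  representation(name = "character", genomeId = "character",
                 genomeStart = "numeric", strand = "character",
                 utr5 = "numeric", cds = "numeric", utr3 = "numeric"))

setValidity("TranscriptModel", function(object) {
  msgs <- character(0)
  if (!object@strand %in% c("+", "-")) msgs <- c(msgs, "strand must be + or -")
  if (object@utr5 < 0 || object@cds <= 0 || object@utr3 < 0)
    msgs <- c(msgs, "segment lengths must be non-negative (cds positive)")
  if (object@genomeStart < 1) msgs <- c(msgs, "genomeStart must be >= 1")
  if (length(msgs) == 0L) TRUE else msgs
})

#' An RNA cleavage event
#'
#' Describes a cleaved transcript by the 3' end of the 5' product
#' (`fiveEnd`), the 5' end of the 3' product (`threeStart`) and any
#' untemplated bases observed at the 5'-product 3' end. The intervening gap
#' is `threeStart - fiveEnd - 1` nucleotides (the segment lost to cleavage
#' plus exonucleolytic trimming).
#'
#' @slot fiveEnd coordinate of the 3' end of the 5' product (1-based).
#' @slot threeStart coordinate of the 5' end of the 3' product.
#' @slot untemplated untemplated bases (e.g. `"A"`, `"AA"`) or `""`.
#' @seealso [gapLength()], [inferCleavage()], [predictFragments()]
#' @export
setClass("CleavageEvent",
  representation(fiveEnd = "numeric", threeStart = "numeric",
                 untemplated = "character"),
  prototype(untemplated = ""))

setValidity("CleavageEvent", function(object) {
  if (object@threeStart <= object@fiveEnd)
    return("threeStart must be greater than fiveEnd (gap >= 0)")
  TRUE
})

#' Map of mapped transcript ends
#'
#' Per-coordinate clone counts of mapped 5' and 3' ends, split by method
#' (cRT-PCR or RACE), over a window of interest. Coordinates falling outside
#' the window are retained and flagged, never dropped silently.
#'
#' @slot ends `data.frame` with columns `coord`, `end_class` (`"5prime"` /
#'   `"3prime"`), `method`, `count`, `in_window`.
#' @slot window numeric length-2 inclusive interval.
#' @export
setClass("EndMap",
  representation(ends = "data.frame", window = "numeric"))

setValidity("EndMap", function(object) {
  e <- object@ends
  need <- c("coord", "end_class", "method", "count", "in_window")
  if (!all(need %in% colnames(e)))
    return(paste("ends must have columns", paste(need, collapse = ", ")))
  if (nrow(e) > 0L && any(e$count < 0)) return("counts must be >= 0")
  if (length(object@window) != 2L || object@window[2L] < object@window[1L])
    return("window must be an increasing length-2 interval")
  TRUE
})
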