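# The PPR code: residue pair -> base preference, and match classification.

#' Load a PPR code table
#'
#' Reads a code table from a YAML (or JSON) configuration with a `pairs` map
#' and optional `default_policy`, or returns the shipped default table when
#' called with no argument. The default table carries the canonical P-class
#' combinations (T,N)->A, (T,D)->G, (N,D)->U, (N,N)->C (U partial),
#' (S,N)->A and (S,D)->G; unlisted pairs are treated as partial on all four
#' bases so that uninformative motifs never create spurious mismatches.
#'
#' @param path path to a YAML/JSON config, or `NULL` for the shipped default.
#' @return a validated [CodeTable-class].
#' @examples
#' tbl <- loadCodeTable()
#' classifyMatch(c("T", "D"), "G", tbl)
#' @export
loadCodeTable <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ppr_code.yaml", package = "pprtarget",
                        mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$pairs) || length(cfg$pairs) == 0L)
    stop("code table config must contain a non-empty 'pairs' map", call. = FALSE)
  entries <- lapply(names(cfg$pairs), function(key) {
    e <- cfg$pairs[[key]]
    prim <- .asRNA(unlist(e$primary))
    seco <- .asRNA(unlist(e$secondary))
    bad <- setdiff(c(prim, seco), RNA_BASES)
    if (length(bad) > 0L)
      stop("code table entry (", key, "): invalid base(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    list(primary = prim, secondary = if (length(seco)) seco else character(0))
  })
  names(entries) <- gsub("[[:space:]]", "", names(cfg$pairs))
  policy <- if (is.null(cfg$default_policy)) "partial-all" else cfg$default_policy
  new("CodeTable", entries = entries, defaultPolicy = policy)
}

#' @keywords internal
#' @noRd
.pairKey <- function(res5, res35) paste(toupper(res5), toupper(res35), sep = ",")

#' Bases recognized by a residue pair
#'
#' @param res5,res35 one-letter specificity residues.
#' @param table a [CodeTable-class].
#' @return list with elements `primary` and `secondary` (character vectors of
#'   RNA bases).
#' @export
codeEntry <- function(res5, res35, table) {
  e <- table@entries[[.pairKey(res5, res35)]]
  if (is.null(e)) {
    if (table@defaultPolicy == "partial-all") {
      e <- list(primary = character(0), secondary = RNA_BASES)
    } else {
      e <- list(primary = character(0), secondary = character(0))
    }
  }
  e
}

#' Classify a motif-base match
#'
#' Applies the three-class match model of the PPR code: `PERFECT` when the
#' base is in the pair's primary set, `PARTIAL` when in the secondary set,
#' `MISMATCH` otherwise. Unlisted residue pairs follow the table's default
#' policy.
#'
#' @param motif a single-row motif (a [PPRArray-class] motif row, a list with
#'   `res5`/`res35`, or a length-2 character vector `c(res5, res35)`).
#' @param base a single RNA base (`A`, `C`, `G`, `U`; `T` accepted).
#' @param table a [CodeTable-class].
#' @return `"PERFECT"`, `"PARTIAL"` or `"MISMATCH"`.
#' @export
classifyMatch <- function(motif, base, table) {
  if (is.character(motif) && length(motif) == 2L)
    motif <- list(res5 = motif[1L], res35 = motif[2L])
  base <- .checkBases(base)
  if (length(base) != 1L) stop("base must be a single nucleotide", call. = FALSE)
  e <- codeEntry(motif$res5, motif$res35, table)
  if (base %in% e$primary) "PERFECT"
  else if (base %in% e$secondary) "PARTIAL"
  else "MISMATCH"
}

# match weights fixed by the three-class model
MATCH_WEIGHTS <- c(PERFECT = 1.0, PARTIAL = 0.5, MISMATCH = 0.0)

#' Predict the recognition sequence of a PPR array
#'
#' One base-preference entry per motif, with the N-terminal motif pairing
#' with the 5'-most target base. Use [iupacString()] to render the prediction
#' as a degenerate string: strict mode uses primary bases only, loose mode
#' the union of primary and secondary bases.
#'
#' @param array a [PPRArray-class] with at least one motif.
#' @param table a [CodeTable-class].
#' @return a [RecognitionSequence-class].
#' @export
predictRecognition <- function(array, table) {
  stopifnot(is(array, "PPRArray"))
  m <- array@motifs
  if (nrow(m) == 0L) stop("array has no motifs", call. = FALSE)
  ent <- lapply(seq_len(nrow(m)),
                function(i) codeEntry(m$res5[i], m$res35[i], table))
  new("RecognitionSequence",
      primary = lapply(ent, `[[`, "primary"),
      secondary = lapply(ent, `[[`, "secondary"))
}

#' Render a recognition sequence as an IUPAC string
#'
#' @param rs a [RecognitionSequence-class].
#' @param mode `"strict"` (primary bases only) or `"loose"` (primary union
#'   secondary).
#' @return a single IUPAC string (RNA alphabet); positions with an empty base
#'   set render as `N`.
#' @export
iupacString <- function(rs, mode = c("strict", "loose")) {
  mode <- match.arg(mode)
  sets <- if (mode == "strict") rs@primary
          else mapply(function(p, s) union(p, s), rs@primary, rs@secondary,
                      SIMPLIFY = FALSE)
  paste(vapply(sets, .setToIupac, character(1L)), collapse = "")
}

#' Score a PPR array against an RNA window
#'
#' Classifies every motif-base pair and sums the match weights
#' (PERFECT = 1, PARTIAL = 0.5, MISMATCH = 0). The window must be exactly as
#' long as the array (one base per motif), written 5' to 3'.
#'
#' @param array a [PPRArray-class].
#' @param window RNA string of length equal to the motif count.
#' @param table a [CodeTable-class].
#' @return a [PPRAlignment-class] with per-motif classes and the total score.
#' @export
scoreAlignment <- function(array, window, table) {
  stopifnot(is(array, "PPRArray"))
  m <- array@motifs
  bases <- .splitRNA(window)
  if (length(bases) != nrow(m))
    stop("window length (", length(bases), ") must equal motif count (",
         nrow(m), ")", call. = FALSE)
  .checkBases(bases)
  classes <- vapply(seq_len(nrow(m)), function(i) {
    classifyMatch(list(res5 = m$res5[i], res35 = m$res35[i]), bases[i], table)
  }, character(1L))
  new("PPRAlignment", classes = classes,
      score = sum(MATCH_WEIGHTS[classes]))
}

# fast per-position weight/class machinery used by the genome scanner:
# returns a 4 x n matrix of weights, rows = A,C,G,U, columns = motifs
#' @keywords internal
#' @noRd
.weightMatrix <- function(array, table) {
  m <- array@motifs
  w <- matrix(0, nrow = 4L, ncol = nrow(m),
              dimnames = list(RNA_BASES, NULL))
  for (i in seq_len(nrow(m))) {
    e <- codeEntry(m$res5[i], m$res35[i], table)
    w[e$primary, i] <- 1.0
    w[e$secondary, i] <- 0.5
  }
  w
}
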