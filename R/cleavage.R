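# Transcript models, clone decomposition (cRT-PCR junctions, 5'-RACE),
# end maps and cleavage-event inference.

#' Construct a transcript model
#'
#' @param name transcript name.
#' @param genomeId genome identifier.
#' @param genomeStart 1-based genome coordinate of the transcript 5' end.
#' @param strand `"+"` or `"-"`.
#' @param utr5,cds,utr3 segment lengths in nt.
#' @return a [TranscriptModel-class].
#' @examples
#' nad6 <- transcriptModel("nad6", "mito", 164694, "+", 179, 601, 0)
#' transcriptLength(nad6)  # 780
#' @export
transcriptModel <- function(name, genomeId, genomeStart, strand = "+",
                            utr5, cds, utr3 = 0) {
  new("TranscriptModel", name = name, genomeId = genomeId,
      genomeStart = as.numeric(genomeStart), strand = strand,
      utr5 = as.numeric(utr5), cds = as.numeric(cds), utr3 = as.numeric(utr3))
}

#' @rdname transcriptModel
#' @param model a [TranscriptModel-class].
#' @return `transcriptLength()`: total mature length `utr5 + cds + utr3`.
#' @export
transcriptLength <- function(model) model@utr5 + model@cds + model@utr3

setMethod("show", "TranscriptModel", function(object) {
  cat("TranscriptModel ", object@name, " (", object@genomeId, object@strand,
      " @", object@genomeStart, "): 5'UTR ", object@utr5, " + CDS ",
      object@cds, " + 3'UTR ", object@utr3, " = ",
      transcriptLength(object), " nt\n", sep = "")
})

#' Convert between transcript and genome coordinates
#'
#' Both systems are 1-based inclusive; transcript position 1 is the mature
#' 5' end. On the minus strand genome coordinates decrease along the
#' transcript.
#'
#' @param model a [TranscriptModel-class].
#' @param pos coordinate vector to convert.
#' @return converted coordinate vector.
#' @export
transcriptToGenome <- function(model, pos) {
  L <- transcriptLength(model)
  if (any(pos < 1 | pos > L))
    stop("transcript position out of range 1..", L, call. = FALSE)
  if (model@strand == "+") model@genomeStart + pos - 1
  else model@genomeStart - pos + 1
}

#' @rdname transcriptToGenome
#' @export
genomeToTranscript <- function(model, pos) {
  tpos <- if (model@strand == "+") pos - model@genomeStart + 1
          else model@genomeStart - pos + 1
  L <- transcriptLength(model)
  if (any(tpos < 1 | tpos > L))
    stop("genome position maps outside the transcript (1..", L, ")",
         call. = FALSE)
  tpos
}

#' Construct a cleavage event
#'
#' @param fiveEnd 3' end of the 5' product (1-based coordinate).
#' @param threeStart 5' end of the 3' product.
#' @param untemplated untemplated bases at the 5'-product 3' end.
#' @return a [CleavageEvent-class].
#' @export
cleavageEvent <- function(fiveEnd, threeStart, untemplated = "") {
  new("CleavageEvent", fiveEnd = as.numeric(fiveEnd),
      threeStart = as.numeric(threeStart), untemplated = untemplated)
}

#' Gap length of a cleavage event
#'
#' The number of nucleotides between the two product ends,
#' `threeStart - fiveEnd - 1` (both end positions exclusive).
#'
#' @param event a [CleavageEvent-class].
#' @return gap length in nt (>= 0).
#' @export
gapLength <- function(event) event@threeStart - event@fiveEnd - 1

setMethod("show", "CleavageEvent", function(object) {
  cat("CleavageEvent: 5' product ends ", object@fiveEnd,
      ", 3' product starts ", object@threeStart,
      " (gap ", gapLength(object), " nt)", sep = "")
  if (nzchar(object@untemplated))
    cat("; untemplated 3' addition '", object@untemplated, "'", sep = "")
  cat("\n")
})

#' Distances from a binding site to a cleavage position
#'
#' The reference point for "n nt downstream of the binding site" is
#' ambiguous in practice, so distances from both the site start and the site
#' end are reported and neither is preferred.
#'
#' @param cleavagePos coordinate of the cleavage position.
#' @param siteStart,siteEnd 1-based inclusive binding-site coordinates.
#' @return named numeric vector `from_site_start`, `from_site_end`.
#' @export
cleavageDistances <- function(cleavagePos, siteStart, siteEnd) {
  c(from_site_start = cleavagePos - siteStart,
    from_site_end = cleavagePos - siteEnd)
}

# exact-anchor helpers -------------------------------------------------------

# all start positions of exact occurrences of `word` in `s` (character ops)
#' @keywords internal
#' @noRd
.occurrences <- function(word, s) {
  m <- gregexpr(word, s, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

# forward extension length of clone[from..] against transcript[tpos..]
#' @keywords internal
#' @noRd
.extendForward <- function(clone, from, transcript, tpos) {
  n <- length(clone); L <- length(transcript)
  l <- 0L
  while (from + l <= n && tpos + l <= L &&
         clone[from + l] == transcript[tpos + l]) l <- l + 1L
  l
}

# backward extension length ending at clone[to] / transcript[tend]
#' @keywords internal
#' @noRd
.extendBackward <- function(clone, to, transcript, tend) {
  l <- 0L
  while (to - l >= 1L && tend - l >= 1L &&
         clone[to - l] == transcript[tend - l]) l <- l + 1L
  l
}

#' Decompose a circular RT-PCR junction clone
#'
#' A cRT-PCR clone reads across the ligation junction of a circularized
#' molecule: its prefix is the 3' part of the molecule (ending at the
#' molecule's 3' end) and its suffix is the 5' part (starting at the
#' molecule's 5' end). Both anchors must match the reference transcript
#' exactly over at least `minAnchor` nt. Bases at the junction assignable to
#' neither anchor are returned as the untemplated insert; when a base could
#' extend either anchor, the 5'-end (suffix) anchor wins, so untemplated
#' additions are reported on the 3' end of the upstream product, where they
#' occur biologically.
#'
#' @param clone clone sequence (RNA/DNA spelling).
#' @param transcript the full uncleaved reference transcript.
#' @param minAnchor minimum exact anchor length (default 12 nt).
#' @return list with `threeEnd` (transcript coordinate of the molecule 3'
#'   end), `fiveEnd` (coordinate of the molecule 5' end) and `untemplated`
#'   (insert string, possibly `""`).
#' @examples
#' tx <- paste(rep(c("ACGUACGUGC", "UGCAUGGACU"), 5), collapse = "")
#' clone <- paste0(substr(tx, 81, 100), substr(tx, 1, 20))
#' decomposeClone(clone, tx)  # intact circularized molecule: 100, 1
#' @export
decomposeClone <- function(clone, transcript, minAnchor = 12L) {
  cloneStr <- .asRNA(clone); txStr <- .asRNA(transcript)
  n <- nchar(cloneStr)
  if (n < 2L * minAnchor)
    stop("unmappable clone: shorter than twice the minimum anchor (",
         2L * minAnchor, " nt)", call. = FALSE)
  cl <- strsplit(cloneStr, "", fixed = TRUE)[[1L]]
  tx <- strsplit(txStr, "", fixed = TRUE)[[1L]]

  # candidate prefix anchors: seed on the clone's first minAnchor bases
  prefSeed <- substr(cloneStr, 1L, minAnchor)
  prefCand <- lapply(.occurrences(prefSeed, txStr), function(x) {
    len <- minAnchor + .extendForward(cl, minAnchor + 1L, tx, x + minAnchor)
    list(tstart = x, len = len)
  })
  # candidate suffix anchors: seed on the clone's last minAnchor bases
  sufSeed <- substr(cloneStr, n - minAnchor + 1L, n)
  sufCand <- lapply(.occurrences(sufSeed, txStr), function(y) {
    tend <- y + minAnchor - 1L
    len <- minAnchor +
      .extendBackward(cl, n - minAnchor, tx, tend - minAnchor)
    list(tend = tend, len = len)
  })
  if (length(prefCand) == 0L || length(sufCand) == 0L)
    stop("unmappable clone: no exact anchor of length >= ", minAnchor,
         call. = FALSE)

  best <- NULL
  for (sf in sufCand) {
    cloneSufStart <- n - sf$len + 1L          # clone position where suffix begins
    for (pf in prefCand) {
      # prefix may not run into the suffix on the clone
      plen <- min(pf$len, cloneSufStart - 1L)
      if (plen < minAnchor) next
      cand <- list(threeEnd = pf$tstart + plen - 1L,
                   fiveEnd = sf$tend - sf$len + 1L,
                   insert = substr(cloneStr, plen + 1L, cloneSufStart - 1L),
                   suflen = sf$len, preflen = plen)
      if (is.null(best) ||
          cand$suflen > best$suflen ||
          (cand$suflen == best$suflen && cand$preflen > best$preflen)) {
        best <- cand
      }
    }
  }
  if (is.null(best))
    stop("unmappable clone: anchors overlap beyond the minimum anchor length",
         call. = FALSE)
  list(threeEnd = best$threeEnd, fiveEnd = best$fiveEnd,
       untemplated = best$insert)
}

#' Map a 5'-RACE clone to a transcript 5' end
#'
#' Finds the longest contiguous exact match of the clone's 3'-terminal
#' anchor in the transcript, extends it 5'-wards, and returns the transcript
#' position of the 5'-most matched base; any non-matching clone prefix (the
#' RACE adapter) is trimmed.
#'
#' @inheritParams decomposeClone
#' @return transcript coordinate of the mapped 5' end.
#' @export
mapRaceEnd <- function(clone, transcript, minAnchor = 12L) {
  cloneStr <- .asRNA(clone); txStr <- .asRNA(transcript)
  n <- nchar(cloneStr)
  if (n < minAnchor)
    stop("unmappable clone: shorter than the minimum anchor", call. = FALSE)
  cl <- strsplit(cloneStr, "", fixed = TRUE)[[1L]]
  tx <- strsplit(txStr, "", fixed = TRUE)[[1L]]
  seed <- substr(cloneStr, n - minAnchor + 1L, n)
  occ <- .occurrences(seed, txStr)
  if (length(occ) == 0L)
    stop("unmappable clone: no exact anchor of length >= ", minAnchor,
         call. = FALSE)
  lens <- vapply(occ, function(y) {
    tend <- y + minAnchor - 1L
    minAnchor + .extendBackward(cl, n - minAnchor, tx, tend - minAnchor)
  }, integer(1L))
  k <- which.max(lens)
  (occ[k] + minAnchor - 1L) - lens[k] + 1L
}

#' Tally mapped transcript ends into an end map
#'
#' @param decompositions `data.frame` (or list coercible to one) with
#'   columns `three_end`, `five_end` (either may be `NA`) and `method`
#'   (`"cRT-PCR"` or `"RACE"`), one row per mappable clone.
#' @param window length-2 inclusive coordinate interval of interest (e.g.
#'   the region around a predicted binding site). Ends outside the window
#'   are kept and flagged `in_window = FALSE`.
#' @return an [EndMap-class].
#' @export
summarizeEnds <- function(decompositions, window) {
  d <- as.data.frame(decompositions)
  rows <- list()
  if (nrow(d) > 0L) {
    for (cls in c("5prime", "3prime")) {
      col <- if (cls == "5prime") "five_end" else "three_end"
      keep <- !is.na(d[[col]])
      if (!any(keep)) next
      agg <- stats::aggregate(list(count = rep(1L, sum(keep))),
                              by = list(coord = d[[col]][keep],
                                        method = d$method[keep]),
                              FUN = sum)
      agg$end_class <- cls
      rows[[length(rows) + 1L]] <- agg
    }
  }
  ends <- if (length(rows)) do.call(rbind, rows) else
    data.frame(coord = numeric(0), method = character(0),
               count = integer(0), end_class = character(0))
  ends$in_window <- ends$coord >= window[1L] & ends$coord <= window[2L]
  ends <- ends[order(ends$coord, ends$end_class, ends$method),
               c("coord", "end_class", "method", "count", "in_window")]
  rownames(ends) <- NULL
  new("EndMap", ends = ends, window = as.numeric(window))
}

#' @rdname summarizeEnds
#' @param endmap an [EndMap-class].
#' @return `endCounts()`: the tidy per-coordinate count table.
#' @export
endCounts <- function(endmap) endmap@ends

setMethod("show", "EndMap", function(object) {
  cat("EndMap over window [", object@window[1L], ", ", object@window[2L],
      "] with ", sum(object@ends$count), " mapped end(s)\n", sep = "")
  if (nrow(object@ends) > 0L) print(object@ends)
})

#' Infer the cleavage event from an end map
#'
#' Picks the modal in-window 3' end (the 5'-product terminus) and the modal
#' in-window 5' end (the 3'-product start) by plurality of clone counts;
#' count ties are broken toward the larger gap, with a warning. Whether the
#' gap arises from a double endonucleolytic cut or a single cut followed by
#' exonucleolytic trimming is an interpretation (`model` argument) and does
#' not change the inferred coordinates.
#'
#' @param endmap an [EndMap-class].
#' @param model `"trim"` (single cut plus 3'-5' trimming; default) or
#'   `"double"` (two cuts); recorded for interpretation only.
#' @return a [CleavageEvent-class].
#' @export
inferCleavage <- function(endmap, model = c("trim", "double")) {
  model <- match.arg(model)
  e <- endmap@ends[endmap@ends$in_window, , drop = FALSE]
  pick <- function(cls, towardLargerGap) {
    sub <- e[e$end_class == cls, , drop = FALSE]
    if (nrow(sub) == 0L)
      stop("end map has no in-window ", cls, " ends", call. = FALSE)
    tot <- stats::aggregate(list(count = sub$count),
                            by = list(coord = sub$coord), FUN = sum)
    mx <- tot[tot$count == max(tot$count), , drop = FALSE]
    if (nrow(mx) > 1L) {
      warning("tie among modal ", cls, " ends; choosing the one giving the ",
              "larger gap", call. = FALSE)
    }
    if (towardLargerGap) min(mx$coord) else max(mx$coord)
  }
  a <- pick("3prime", towardLargerGap = TRUE)
  b <- pick("5prime", towardLargerGap = FALSE)
  if (b <= a)
    stop("modal 5' end (", b, ") does not lie 3' of the modal 3' end (", a,
         "); cannot form a cleavage event", call. = FALSE)
  cleavageEvent(a, b)
}

#' Predict northern fragment sizes for a cleavage event
#'
#' Computes, from a transcript model and a cleavage event in genome
#' coordinates, the mature full length and the lengths of the 5' and 3'
#' cleavage products. The three quantities obey
#' `five + gap + three = full`.
#'
#' @param model a [TranscriptModel-class].
#' @param event a [CleavageEvent-class] in the model's genome coordinates.
#' @return named numeric vector `five_prime_fragment`,
#'   `three_prime_fragment`, `full_length`.
#' @export
predictFragments <- function(model, event) {
  t5 <- genomeToTranscript(model, event@fiveEnd)
  t3 <- genomeToTranscript(model, event@threeStart)
  if (t3 <= t5)
    stop("event coordinates are inverted on this transcript strand",
         call. = FALSE)
  L <- transcriptLength(model)
  c(five_prime_fragment = t5,
    three_prime_fragment = L - t3 + 1,
    full_length = L)
}
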