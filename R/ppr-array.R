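# Constructors, accessors and I/O for PPR motif arrays.

#' Construct a PPR array
#'
#' Builds a [PPRArray-class] from vectors of specificity residues. When spans
#' are omitted, consecutive non-overlapping 35-residue spans are assumed
#' (motif i occupies residues `35*(i-1)+1 .. 35*i`), matching the canonical
#' P-motif length.
#'
#' @param name array identifier.
#' @param res5,res35 character vectors of one-letter residues, one per motif,
#'   N- to C-terminal.
#' @param spanStart,spanEnd optional integer vectors of residue coordinates.
#' @param proteinSeq optional full amino-acid sequence.
#' @return a validated [PPRArray-class].
#' @examples
#' arr <- pprArray("toy", res5 = c("T", "T"), res35 = c("D", "N"))
#' iupacString(predictRecognition(arr, loadCodeTable()))
#' @export
pprArray <- function(name, res5, res35, spanStart = NULL, spanEnd = NULL,
                     proteinSeq = NA_character_) {
  n <- length(res5)
  if (length(res35) != n) stop("res5 and res35 lengths differ", call. = FALSE)
  if (is.null(spanStart)) spanStart <- 35L * (seq_len(n) - 1L) + 1L
  if (is.null(spanEnd)) spanEnd <- spanStart + 34L
  motifs <- data.frame(index = seq_len(n),
                       res5 = toupper(res5), res35 = toupper(res35),
                       span_start = as.integer(spanStart),
                       span_end = as.integer(spanEnd),
                       stringsAsFactors = FALSE)
  new("PPRArray", name = name, motifs = motifs,
      proteinSeq = if (is.na(proteinSeq)) NA_character_ else toupper(proteinSeq))
}

#' @describeIn pprArray number of motifs in the array.
#' @param x,object a `PPRArray`.
#' @export
setMethod("length", "PPRArray", function(x) nrow(x@motifs))

#' Motif table of a PPR array
#' @param array a [PPRArray-class].
#' @return the motif `data.frame`.
#' @export
motifs <- function(array) {
  stopifnot(is(array, "PPRArray"))
  array@motifs
}

#' Protein sequence of a PPR array
#' @param array a [PPRArray-class].
#' @return the amino-acid string, or `NA` if absent.
#' @export
proteinSeq <- function(array) {
  stopifnot(is(array, "PPRArray"))
  array@proteinSeq
}

setMethod("show", "PPRArray", function(object) {
  cat("PPRArray '", object@name, "' with ", nrow(object@motifs),
      " motif(s)\n", sep = "")
  pairs <- paste0("(", object@motifs$res5, ",", object@motifs$res35, ")")
  cat("  residues 5/35:", paste(pairs, collapse = " "), "\n")
  if (!is.na(object@proteinSeq))
    cat("  protein: ", nchar(object@proteinSeq), " aa\n", sep = "")
})

setMethod("show", "CodeTable", function(object) {
  cat("CodeTable with", length(object@entries), "residue pair(s); unlisted ->",
      object@defaultPolicy, "\n")
  for (key in names(object@entries)) {
    e <- object@entries[[key]]
    cat("  (", key, ") primary {", paste(e$primary, collapse = ","),
        "} secondary {", paste(e$secondary, collapse = ","), "}\n", sep = "")
  }
})

setMethod("show", "RecognitionSequence", function(object) {
  cat("RecognitionSequence (", length(object@primary), " motifs)\n", sep = "")
  cat("  strict: ", iupacString(object, "strict"), "\n", sep = "")
  cat("  loose : ", iupacString(object, "loose"), "\n", sep = "")
})

setMethod("show", "PPRAlignment", function(object) {
  tag <- c(PERFECT = "=", PARTIAL = "~", MISMATCH = "x")
  cat("PPRAlignment score ", object@score, " / ", length(object@classes),
      "\n  ", paste(tag[object@classes], collapse = ""), "\n", sep = "")
})

#' Read a PPR array from TSV
#'
#' The TSV must carry columns `index`, `res5`, `res35`, `span_start`,
#' `span_end`. An optional FASTA supplies the parent protein sequence, which
#' is checked against the motif annotations.
#'
#' @param path TSV file path.
#' @param name array name; defaults to the file base name.
#' @param proteinFasta optional FASTA with a single amino-acid record.
#' @return a [PPRArray-class].
#' @export
readPPRArray <- function(path, name = NULL, proteinFasta = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("index", "res5", "res35", "span_start", "span_end")
  if (!all(need %in% colnames(tab)))
    stop("PPR array TSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  prot <- NA_character_
  if (!is.null(proteinFasta)) {
    aa <- Biostrings::readAAStringSet(proteinFasta)
    prot <- as.character(aa[[1L]])
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  pprArray(name, tab$res5, tab$res35, tab$span_start, tab$span_end, prot)
}

#' Write a PPR array to TSV
#' @param array a [PPRArray-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writePPRArray <- function(array, path) {
  stopifnot(is(array, "PPRArray"))
  utils::write.table(array@motifs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
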