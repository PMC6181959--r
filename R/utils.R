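# Internal sequence helpers shared across modules. All sequences are held
# internally as RNA (A, C, G, U, N); T is converted at entry points.

RNA_BASES <- c("A", "C", "G", "U")

AA_ALPHABET1 <- c("A","R","N","D","C","Q","E","G","H","I",
                  "L","K","M","F","P","S","T","W","Y","V","X")

# IUPAC classes over the RNA alphabet
IUPAC_RNA <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"),
  S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"),
  H = c("A", "C", "U"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "U")
)

#' @keywords internal
#' @noRd
.asRNA <- function(x) {
  x <- toupper(as.character(x))
  chartr("T", "U", x)
}

#' @keywords internal
#' @noRd
.asDNA <- function(x) {
  chartr("U", "T", toupper(as.character(x)))
}

# integer encoding A=1 C=2 G=3 U=4, anything else NA
#' @keywords internal
#' @noRd
.encodeRNA <- function(x) {
  match(strsplit(.asRNA(x), "", fixed = TRUE)[[1L]], RNA_BASES)
}

#' @keywords internal
#' @noRd
.splitRNA <- function(x) strsplit(.asRNA(x), "", fixed = TRUE)[[1L]]

# deterministic base-set -> IUPAC letter
#' @keywords internal
#' @noRd
.setToIupac <- function(bases) {
  bases <- sort(unique(.asRNA(bases)))
  if (length(bases) == 0L) return("N")
  for (code in names(IUPAC_RNA)) {
    if (identical(sort(IUPAC_RNA[[code]]), bases)) return(code)
  }
  stop("no IUPAC code for base set {", paste(bases, collapse = ","), "}")
}

#' @keywords internal
#' @noRd
.checkBases <- function(bases, what = "base") {
  bases <- .asRNA(bases)
  bad <- setdiff(bases, RNA_BASES)
  if (length(bad) > 0L) {
    stop("invalid ", what, ": ", paste(bad, collapse = ", "),
         " (must be one of A, C, G, U)", call. = FALSE)
  }
  bases
}

# reverse complement on RNA character strings
#' @keywords internal
#' @noRd
.revCompRNA <- function(x) {
  vapply(x, function(s) {
    chars <- rev(.splitRNA(s))
    paste(chartr("ACGUN", "UGCAN", chars), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# run code under a fixed seed without disturbing the caller's RNG stream
#' @keywords internal
#' @noRd
.withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' @keywords internal
#' @noRd
.pasteBases <- function(chars) paste(chars, collapse = "")
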