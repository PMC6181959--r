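# A synthetic stand-in for the Col-0 mitochondrial reference (GenBank
# JF729201, 367,808 bp), built entirely in code. The background sequence is
# random; what is real are the published coordinates and the match/mismatch
# structure of the planted loci, so that coordinate arithmetic, scans and
# pattern searches reproduce the published numbers on a sequence we are free
# to ship. All sequences here are synthetic and must not be mistaken for the
# actual genome.

SYNTH_GENOME_LENGTH <- 367808L
SYNTH_GENOME_SEED <- 20181011L   # fixed: the reference is a fixed object

# planted site sequences (RNA). The published degenerate pattern
# 'NAAAURCGACCUNUCY' is matched exactly by the nad6 design site, with one
# C-U mismatch by the rps3 site, and with >= 2 mismatches by the cox3/nad9
# natural sites (which the published transcriptome search did not hit).
PPR_PATTERN <- "NAAAURCGACCUNUCY"
SITE_NAD6_16 <- "AAAAUACGACCUAUCC"   # design target, genome 165,221-165,236
SITE_COX3_16 <- "AGAACACGUCCUAUCC"   # natural target, 3 diffs to nad6 window
SITE_NAD9_16 <- "AGAAUACGUCCUAUCU"   # natural target (minus-strand locus)
SITE_RPS3_16 <- "AAAAUACGACCUAUUC"   # off-target, one C-U mismatch to pattern
SITE_EXTRA17 <- "G"                  # 17th base of the cox3/nad6 windows

#' A synthetic RPF2-like PPR array
#'
#' Sixteen P-class motifs whose strict recognition sequence equals the
#' synthetic cox3 natural site, using the canonical code pairs
#' (A -> (T,N), G -> (T,D), C -> (N,N), U -> (N,D)). A deterministic parent
#' protein sequence (16 x 35 aa) consistent with the motif annotations is
#' attached. The residue content is synthetic: the real protein's specificity
#' residues are not modelled, only the array geometry and code behaviour.
#'
#' @return a [PPRArray-class] of 16 motifs.
#' @export
rpf2LikeArray <- function() {
  baseToPair <- list(A = c("T", "N"), G = c("T", "D"),
                     C = c("N", "N"), U = c("N", "D"))
  bases <- .splitRNA(SITE_COX3_16)
  res5 <- vapply(bases, function(b) baseToPair[[b]][1L], character(1L))
  res35 <- vapply(bases, function(b) baseToPair[[b]][2L], character(1L))
  prot <- .withSeed(7L, {
    aa <- sample(setdiff(AA_ALPHABET1, "X"), 35L * 16L, replace = TRUE)
    for (i in seq_len(16L)) {
      aa[35L * (i - 1L) + 5L] <- res5[i]
      aa[35L * (i - 1L) + 35L] <- res35[i]
    }
    paste(aa, collapse = "")
  })
  pprArray("RPF2-like", res5, res35, proteinSeq = prot)
}

#' @keywords internal
#' @noRd
.synthModels <- function() {
  list(
    nad6 = transcriptModel("nad6", "mito_synthetic", 164694, "+", 179, 601, 0),
    cox3 = transcriptModel("cox3", "mito_synthetic", 85000, "+", 600, 798, 100),
    nad9 = transcriptModel("nad9", "mito_synthetic", 245000, "-", 400, 573, 80),
    rps3 = transcriptModel("rps3", "mito_synthetic", 60000, "+", 150, 2400, 150)
  )
}

# genome intervals that sanitization must never touch
#' @keywords internal
#' @noRd
.synthProtected <- function() {
  rbind(c(165221L, 165237L),   # nad6 site + 17th base
        c(165268L, 165268L),   # junction context base

        c(85129L, 85145L),     # cox3 site + 17th base
        c(244886L, 244901L),   # nad9 site (minus strand)
        c(61499L, 61514L))     # rps3 site
}

#' Synthetic stand-in for the Col-0 mitochondrial genome
#'
#' Builds, from a fixed seed, a 367,808-bp random genome into which the
#' package's reference loci are planted at the published coordinates: the
#' nad6 transcript (179 nt 5'-UTR + 601 nt CDS, no 3'-UTR, 5' end at
#' 164,694) with the 16-nt design binding site at 165,221-165,236
#' (CDS +349-364, with the display window +349-365); a cox3 locus whose
#' natural binding site lies 471-455 nt upstream of the start codon and
#' differs from the nad6 window at exactly 3 of 17 positions; a minus-strand
#' nad9 locus with its site 301-286 nt upstream of the start codon; an rps3
#' locus carrying a site with exactly one C-U mismatch to the degenerate
#' pattern `NAAAURCGACCUNUCY`; and 29 additional random transcripts for a
#' 33-transcript transcriptome. The background is then sanitized so that no
#' spurious window matches the pattern with fewer than two mismatches on
#' either strand, mirroring the uniqueness observed in the real
#' transcriptome search. Everything is generated in code; no real genome
#' sequence is shipped or used.
#'
#' @param nExtra number of additional random transcripts (default 29).
#' @return list with `genome` (named character, DNA), `transcripts` (named
#'   [Biostrings::RNAStringSet], sense strands), `models` (named list of
#'   [TranscriptModel-class]), `sites` (`data.frame` of planted site truth),
#'   `pattern` (the degenerate audit pattern), `designTarget`, and `event`
#'   (the published-coordinate [CleavageEvent-class], genome coordinates).
#' @export
syntheticMitoGenome <- function(nExtra = 29L) {
  key <- paste0("n", nExtra)
  if (!is.null(.synthCache[[key]])) return(.synthCache[[key]])
  models <- .synthModels()
  extraNames <- c("nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad7",
                  "cob", "cox1", "cox2", "atp1", "atp4", "atp6", "atp8",
                  "atp9", "ccmB", "ccmC", "ccmFc", "ccmFn", "matR", "mttB",
                  "rpl2", "rpl5", "rpl16", "rps4", "rps7", "rps12",
                  "rrn18", "rrn26")[seq_len(nExtra)]

  g <- .withSeed(SYNTH_GENOME_SEED, {
    chars <- sample(c("A", "C", "G", "T"), SYNTH_GENOME_LENGTH,
                    replace = TRUE, prob = c(0.275, 0.225, 0.225, 0.275))

    writeDNA <- function(chars, start, rna, revcomp = FALSE) {
      s <- if (revcomp) .revCompRNA(rna) else rna
      sub <- strsplit(.asDNA(s), "", fixed = TRUE)[[1L]]
      chars[start:(start + length(sub) - 1L)] <- sub
      chars
    }
    chars <- writeDNA(chars, 165221L, paste0(SITE_NAD6_16, SITE_EXTRA17))
    # defined junction context one base 5' of the cleavage position
    # (165,269), so that circular-ligation junctions at the modal product
    # ends are unambiguous: the base differs from the transcript's 3'
    # terminal base, from A (untemplated tails) and from the RACE adapter G
    chars[165268L] <- "C"
    chars <- writeDNA(chars, 85129L, paste0(SITE_COX3_16, SITE_EXTRA17))
    chars <- writeDNA(chars, 244886L, SITE_NAD9_16, revcomp = TRUE)
    chars <- writeDNA(chars, 61499L, SITE_RPS3_16)

    # place the extra transcript loci in fixed slots clear of planted loci
    planted <- rbind(c(59900L, 62800L), c(84900L, 86600L),
                     c(164600L, 165600L), c(243800L, 245100L))
    slots <- 2000L + (0:49) * 6500L
    ok <- vapply(slots, function(s) {
      all(s + 2700L < planted[, 1L] | s > planted[, 2L])
    }, logical(1L))
    slots <- slots[ok][seq_along(extraNames)]
    for (i in seq_along(extraNames)) {
      u5 <- sample(50:300, 1L); u3 <- sample(0:150, 1L)
      cds <- sample(300:2000, 1L)
      st <- sample(c("+", "-"), 1L)
      len <- u5 + cds + u3
      gStart <- if (st == "+") slots[i] else slots[i] + len - 1L
      models[[extraNames[i]]] <- transcriptModel(
        extraNames[i], "mito_synthetic", gStart, st, u5, cds, u3)
    }
    chars
  })

  genomeStr <- paste(g, collapse = "")
  genomeStr <- .sanitizeGenome(genomeStr)
  genome <- c(mito_synthetic = genomeStr)

  extractTx <- function(model) {
    L <- transcriptLength(model)
    if (model@strand == "+") {
      s <- substr(genomeStr, model@genomeStart, model@genomeStart + L - 1)
      .asRNA(s)
    } else {
      s <- substr(genomeStr, model@genomeStart - L + 1, model@genomeStart)
      .revCompRNA(.asRNA(s))
    }
  }
  txs <- vapply(models, extractTx, character(1L))
  sites <- data.frame(
    name = c("nad6_design", "cox3_natural", "nad9_natural", "rps3_offtarget"),
    seq = c(SITE_NAD6_16, SITE_COX3_16, SITE_NAD9_16, SITE_RPS3_16),
    genome_start = c(165221L, 85129L, 244901L, 61499L),
    genome_end = c(165236L, 85144L, 244886L, 61514L),
    strand = c("+", "+", "-", "+"),
    transcript = c("nad6", "cox3", "nad9", "rps3"),
    tx_start = c(528L, 130L, 100L, 1500L),
    tx_end = c(543L, 145L, 115L, 1515L),
    stringsAsFactors = FALSE)

  out <- list(genome = genome,
              transcripts = Biostrings::RNAStringSet(txs),
              models = models,
              sites = sites,
              pattern = PPR_PATTERN,
              designTarget = SITE_NAD6_16,
              event = cleavageEvent(165236, 165269))
  .synthCache[[key]] <- out
  out
}

# build cache: the reference is deterministic, so keep one copy per session
.synthCache <- new.env(parent = emptyenv())

# remove chance windows that match the audit pattern with < 2 mismatches
# anywhere outside the planted sites, so that planted uniqueness holds by
# construction (as it does in the real transcriptome)
#' @keywords internal
#' @noRd
.sanitizeGenome <- function(genomeStr) {
  protected <- .synthProtected()
  allowedStarts <- c(165221L, 61499L)   # nad6 exact hit, rps3 1-mismatch hit
  isProtected <- function(p) {
    any(p >= protected[, 1L] & p <= protected[, 2L])
  }
  for (iter in 1:25) {
    hits <- iupacSearch(PPR_PATTERN, c(g = genomeStr), maxMismatch = 1,
                        bothStrands = TRUE)
    rogue <- hits[!(hits$start %in% allowedStarts & hits$strand == "+"), ,
                  drop = FALSE]
    if (nrow(rogue) == 0L) return(genomeStr)
    chars <- strsplit(genomeStr, "", fixed = TRUE)[[1L]]
    for (r in seq_len(nrow(rogue))) {
      # break pattern positions 10 and 11 (literal C) for this window
      pos <- if (rogue$strand[r] == "+") rogue$start[r] + c(9L, 10L)
             else rogue$end[r] - c(9L, 10L)
      for (p in pos) {
        if (!isProtected(p))
          chars[p] <- if (rogue$strand[r] == "+") "A" else "T"
      }
    }
    genomeStr <- paste(chars, collapse = "")
  }
  stop("failed to sanitize synthetic genome", call. = FALSE)
}
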