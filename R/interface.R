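# I/O boundary and the umbrella pipeline. Sequences are held internally as
# RNA; files are written back in the alphabet requested. Reports use 1-based
# inclusive coordinates; BED output is 0-based half-open, converted here and
# only here.

#' Read sequences from FASTA
#'
#' Reads DNA or RNA FASTA and normalizes to RNA internally (T -> U).
#'
#' @param path FASTA file.
#' @return a named [Biostrings::RNAStringSet].
#' @export
readSequences <- function(path) {
  if (!file.exists(path))
    stop("input file does not exist: ", path, call. = FALSE)
  x <- Biostrings::readBStringSet(path)
  seqs <- .asRNA(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  Biostrings::RNAStringSet(seqs)
}

#' Write sequences to FASTA
#'
#' @param seqs an `XStringSet` or named character vector.
#' @param path output path.
#' @param alphabet `"RNA"` (default) or `"DNA"` (U -> T on output).
#' @return `path`, invisibly.
#' @export
writeSequences <- function(seqs, path, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  s <- if (is(seqs, "XStringSet")) as.character(seqs) else seqs
  nm <- names(s)
  s <- if (alphabet == "RNA") .asRNA(s) else .asDNA(s)
  names(s) <- nm
  set <- if (alphabet == "RNA") Biostrings::RNAStringSet(s)
         else Biostrings::DNAStringSet(s)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read transcript/feature annotations from GFF3
#'
#' @param path GFF3 file.
#' @return a `GRanges` (via rtracklayer); malformed records raise an error.
#' @export
readGff3 <- function(path) {
  if (!file.exists(path))
    stop("input file does not exist: ", path, call. = FALSE)
  rtracklayer::import(path, format = "gff3")
}

#' Convert between 1-based inclusive and BED half-open coordinates
#'
#' BED intervals are 0-based half-open: a 1-based inclusive interval
#' `[start, end]` becomes `[start - 1, end)`.
#'
#' @param start,end 1-based inclusive coordinates.
#' @return `toBedCoords()`: `data.frame(start, end)` in BED convention;
#'   `fromBedCoords()` inverts it.
#' @export
toBedCoords <- function(start, end) {
  data.frame(start = start - 1L, end = end)
}

#' @rdname toBedCoords
#' @param bedStart,bedEnd BED (0-based half-open) coordinates.
#' @export
fromBedCoords <- function(bedStart, bedEnd) {
  data.frame(start = bedStart + 1L, end = bedEnd)
}

#' Write scan hits as BED6 and TSV
#'
#' The TSV report keeps 1-based inclusive coordinates; the BED6 file is
#' 0-based half-open with the hit metric in the score column.
#'
#' @param hits a hits `DataFrame` from [scanArray()], [findNearMatches()] or
#'   [iupacSearch()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBedHits <- function(hits, path) {
  metric <- if ("score" %in% colnames(hits)) "score" else "mismatches"
  bed <- toBedCoords(hits$start, hits$end)
  df <- data.frame(chrom = hits$seq_id, start = bed$start, end = bed$end,
                   name = paste0("hit", seq_len(nrow(hits))),
                   score = hits[[metric]], strand = hits$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeBedHits
#' @export
writeHitsTsv <- function(hits, path) {
  utils::write.table(as.data.frame(hits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the pipeline end to end
#'
#' Executes the requested stages in the analysis order — simulate the
#' reference data, scan the genome with the re-designed array, report the
#' design, audit off-targets with the degenerate pattern, map cleavage from
#' simulated clones, and estimate fold changes from simulated counts — and
#' writes a manifest capturing seeds, versions and every output file, which
#' is sufficient to re-run the pipeline bit-identically.
#'
#' @param config list (or path to a YAML file) with elements `out_dir`,
#'   `seed`, and `stages` (subset of `"simulate"`, `"scan"`, `"design"`,
#'   `"pattern"`, `"cleavage"`, `"diffexpr"`; empty writes the manifest
#'   only). Optional: `clone_n` (default 200), `min_anchor` (12).
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file does not exist: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  outDir <- config$out_dir
  if (is.null(outDir)) stop("config$out_dir is required", call. = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stages <- config$stages
  if (is.null(stages)) stages <- character(0)

  manifest <- list(package = "pprtarget",
                   version = as.character(utils::packageVersion("pprtarget")),
                   seed = seed, stages = as.list(stages),
                   outputs = list(), summary = list())
  runStage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  addOut <- function(key, path) {
    manifest$outputs[[key]] <<- path
  }

  ref <- NULL
  needRef <- length(intersect(
    c("simulate", "scan", "design", "pattern", "cleavage"), stages)) > 0L
  if (needRef) ref <- syntheticMitoGenome()
  table <- loadCodeTable()

  for (stage in stages) {
    if (stage == "simulate") runStage(stage, function() {
      fa <- file.path(outDir, "transcripts.fa")
      writeSequences(ref$transcripts, fa)
      tsv <- file.path(outDir, "planted_sites.tsv")
      utils::write.table(ref$sites, tsv, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      addOut("transcripts_fasta", fa); addOut("site_truth_tsv", tsv)
      manifest$summary$simulate <<- list(
        n_transcripts = length(ref$transcripts))
    })
    else if (stage == "scan") runStage(stage, function() {
      design <- designRetarget(rpf2LikeArray(), ref$designTarget, table)
      hits <- scanArray(designedArray(design), ref$genome, table,
                        minScore = length(designedArray(design)),
                        bothStrands = TRUE)
      tsv <- file.path(outDir, "genome_scan.tsv")
      bed <- file.path(outDir, "genome_scan.bed")
      writeHitsTsv(hits, tsv); writeBedHits(hits, bed)
      addOut("genome_scan_tsv", tsv); addOut("genome_scan_bed", bed)
      manifest$summary$scan <<- list(
        n_hits = nrow(hits),
        top_hit = if (nrow(hits)) list(seq_id = hits$seq_id[1L],
                                       start = hits$start[1L],
                                       end = hits$end[1L],
                                       score = hits$score[1L]) else NULL)
    })
    else if (stage == "design") runStage(stage, function() {
      design <- designRetarget(rpf2LikeArray(), ref$designTarget, table,
                               naturalTargets = c(cox3 = SITE_COX3_16,
                                                  nad9 = SITE_NAD9_16))
      edits <- file.path(outDir, "design_edits.tsv")
      utils::write.table(designEdits(design), edits, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      arr <- file.path(outDir, "designed_array.tsv")
      writePPRArray(designedArray(design), arr)
      prot <- file.path(outDir, "designed_protein.fa")
      aa <- Biostrings::AAStringSet(
        c(designed = emitProtein(proteinSeq(rpf2LikeArray()), design)))
      Biostrings::writeXStringSet(aa, prot)
      addOut("design_edits_tsv", edits); addOut("designed_array_tsv", arr)
      addOut("designed_protein_fasta", prot)
      manifest$summary$design <<- list(n_edits = nrow(designEdits(design)))
    })
    else if (stage == "pattern") runStage(stage, function() {
      hits <- iupacSearch(ref$pattern, ref$transcripts, maxMismatch = 1)
      tsv <- file.path(outDir, "pattern_hits.tsv")
      writeHitsTsv(hits, tsv)
      addOut("pattern_hits_tsv", tsv)
      manifest$summary$pattern <<- list(
        n_exact = sum(hits$mismatches == 0),
        n_one_mismatch = sum(hits$mismatches == 1))
    })
    else if (stage == "cleavage") runStage(stage, function() {
      model <- ref$models$nad6
      txEvent <- cleavageEvent(
        genomeToTranscript(model, ref$event@fiveEnd),
        genomeToTranscript(model, ref$event@threeStart))
      n <- if (is.null(config$clone_n)) 200L else as.integer(config$clone_n)
      sim <- simulateClones(ref$transcripts[["nad6"]], txEvent, n,
                            seed = seed)
      minAnchor <- if (is.null(config$min_anchor)) 12L
                   else as.integer(config$min_anchor)
      tx <- as.character(ref$transcripts[["nad6"]])
      dec <- lapply(seq_along(sim$clones), function(i) {
        clone <- as.character(sim$clones[[i]])
        meth <- sim$truth$method[i]
        tryCatch({
          if (meth == "RACE") {
            list(three_end = NA_real_,
                 five_end = mapRaceEnd(clone, tx, minAnchor),
                 method = meth)
          } else {
            d <- decomposeClone(clone, tx, minAnchor)
            list(three_end = d$threeEnd, five_end = d$fiveEnd, method = meth)
          }
        }, error = function(e) NULL)
      })
      dec <- do.call(rbind, lapply(Filter(Negate(is.null), dec),
                                   as.data.frame))
      # report in genome coordinates over the published window
      has3 <- !is.na(dec$three_end)
      dec$three_end[has3] <- transcriptToGenome(model, dec$three_end[has3])
      dec$five_end <- transcriptToGenome(model, dec$five_end)
      em <- summarizeEnds(dec, window = c(165200, 165300))
      ev <- inferCleavage(em)
      frag <- predictFragments(model, ev)
      emPath <- file.path(outDir, "end_map.tsv")
      utils::write.table(endCounts(em), emPath, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      evPath <- file.path(outDir, "cleavage_event.json")
      jsonlite::write_json(list(five_prime_product_end = ev@fiveEnd,
                                three_prime_product_start = ev@threeStart,
                                gap_len = gapLength(ev),
                                fragments = as.list(frag)),
                           evPath, auto_unbox = TRUE, digits = NA)
      addOut("end_map_tsv", emPath); addOut("cleavage_event_json", evPath)
      manifest$summary$cleavage <<- list(gap = gapLength(ev),
                                         fragments = as.list(frag))
    })
    else if (stage == "diffexpr") runStage(stage, function() {
      sim <- simulateCounts(defaultCountScenario(), seed = seed)
      lfc <- log2FoldChanges(sim$se, seed = seed)
      tsv <- file.path(outDir, "log2_fold_changes.tsv")
      utils::write.table(as.data.frame(lfc), tsv, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      addOut("log2fc_tsv", tsv)
      manifest$summary$diffexpr <<- list(
        nad6_log2FC = lfc$log2FC[lfc$transcript == "nad6"])
    })
    else stop("unknown stage '", stage, "'", call. = FALSE)
  }

  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
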