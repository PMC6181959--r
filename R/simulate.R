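# Seeded generators for every input the pipeline consumes: transcriptomes
# with planted binding sites, circularized-clone sets from a cleavage model,
# and negative-binomial replicate count matrices with planted fold changes.
# Every generator is a deterministic function of (config, seed).

#' @keywords internal
#' @noRd
.randomRNA <- function(n, baseProbs = c(A = 0.275, C = 0.225,
                                        G = 0.225, U = 0.275)) {
  paste(sample(names(baseProbs), n, replace = TRUE, prob = baseProbs),
        collapse = "")
}

#' @keywords internal
#' @noRd
.mutateAt <- function(chars, positions) {
  for (p in positions) {
    chars[p] <- sample(setdiff(RNA_BASES, chars[p]), 1L)
  }
  chars
}

#' Simulate a transcriptome with planted binding sites
#'
#' Generates random transcripts and plants copies of given site sequences at
#' chosen positions, optionally with an exact number of substitutions placed
#' at seeded positions. A truth table records where each (possibly mutated)
#' site landed.
#'
#' @param config list with elements `n_transcripts`, `length_range`
#'   (length-2), optional `base_probs` (named A/C/G/U probabilities) and
#'   `planted_sites`: a `data.frame` with columns `site` (RNA string),
#'   `transcript` (index), `position` (1-based) and `n_mutations`.
#' @param seed integer seed; the same (config, seed) yields byte-identical
#'   output.
#' @return list with `seqs` (named [Biostrings::RNAStringSet]) and `truth`
#'   (`data.frame` with the planted, possibly mutated, site per row).
#' @export
simulateTranscriptome <- function(config, seed = 1L) {
  n <- config$n_transcripts
  lr <- config$length_range
  bp <- config$base_probs
  if (is.null(bp)) bp <- c(A = 0.275, C = 0.225, G = 0.225, U = 0.275)
  planted <- config$planted_sites
  .withSeed(seed, {
    lens <- sample(seq(lr[1L], lr[2L]), n, replace = TRUE)
    seqs <- vapply(lens, .randomRNA, character(1L), baseProbs = bp)
    names(seqs) <- sprintf("tx%02d", seq_len(n))
    truth <- NULL
    if (!is.null(planted) && nrow(planted) > 0L) {
      rows <- lapply(seq_len(nrow(planted)), function(i) {
        site <- .splitRNA(planted$site[i])
        ti <- planted$transcript[i]
        pos <- planted$position[i]
        if (pos + length(site) - 1L > lens[ti])
          stop("planted site exceeds transcript ", ti, " bounds",
               call. = FALSE)
        nm <- planted$n_mutations[i]
        if (nm > 0L)
          site <- .mutateAt(site, sample(seq_along(site), nm))
        chars <- strsplit(seqs[[ti]], "", fixed = TRUE)[[1L]]
        chars[pos:(pos + length(site) - 1L)] <- site
        seqs[[ti]] <<- paste(chars, collapse = "")
        data.frame(site = planted$site[i], planted = .pasteBases(site),
                   transcript = names(seqs)[ti], position = pos,
                   n_mutations = nm, stringsAsFactors = FALSE)
      })
      truth <- do.call(rbind, rows)
    }
    list(seqs = Biostrings::RNAStringSet(seqs), truth = truth)
  })
}

#' Simulate circularized-clone sequences from a cleavage event
#'
#' Realizes the cleavage model as sequencing clones: cRT-PCR junction clones
#' of the 5' product (prefix ends at the product 3' end, suffix restarts at
#' the transcript 5' end), cRT-PCR clones of the 3' product, and 5'-RACE
#' clones of the 3' product carrying a `GGG` adapter. End positions receive
#' seeded jitter, molecule 3' ends gain 1-3 untemplated adenosines with
#' probability `untemplated_prob`, and uniform substitution errors are
#' applied at `error_rate` per base.
#'
#' @param transcript the uncleaved transcript (RNA string or `XString`).
#' @param event a [CleavageEvent-class] in transcript coordinates.
#' @param n number of clones.
#' @param config list of optional generator settings: `mix` (named
#'   proportions for `crt5`, `crt3`, `race`; default 0.4/0.4/0.2),
#'   `jitter_prob` (probability an end is jittered; default 0.3),
#'   `max_jitter` (default 5), `untemplated_prob` (default 0.2),
#'   `error_rate` (per-base substitution rate; default 1e-4, the scale of
#'   Sanger sequencing of cloned products), `read_len` (default 120).
#' @param seed integer seed.
#' @return list with `clones` (named [Biostrings::RNAStringSet]) and `truth`
#'   (`data.frame` with per-clone type, method, planted ends and untemplated
#'   tail).
#' @export
simulateClones <- function(transcript, event, n, config = list(), seed = 1L) {
  tx <- .asRNA(as.character(transcript))
  L <- nchar(tx)
  a <- event@fiveEnd; b <- event@threeStart
  if (a < 1 || b > L) stop("event does not fit the transcript", call. = FALSE)
  mix <- config$mix
  if (is.null(mix)) mix <- c(crt5 = 0.4, crt3 = 0.4, race = 0.2)
  jp <- config$jitter_prob; if (is.null(jp)) jp <- 0.3
  mj <- config$max_jitter; if (is.null(mj)) mj <- 5L
  pA <- config$untemplated_prob; if (is.null(pA)) pA <- 0.2
  er <- config$error_rate; if (is.null(er)) er <- 1e-4
  rl <- config$read_len; if (is.null(rl)) rl <- 120L

  jitter <- function() {
    if (stats::runif(1L) >= jp) 0L
    else sample(c(-1L, 1L), 1L) * sample(seq_len(mj), 1L)
  }
  tail_a <- function() {
    if (stats::runif(1L) < pA) strrep("A", sample(1:3, 1L)) else ""
  }
  addErrors <- function(s) {
    if (er <= 0) return(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    hit <- which(stats::runif(length(chars)) < er)
    if (length(hit)) chars <- .mutateAt(chars, hit)
    paste(chars, collapse = "")
  }

  .withSeed(seed, {
    if (n == 0L) {
      return(list(clones = Biostrings::RNAStringSet(),
                  truth = data.frame(type = character(0),
                                     method = character(0),
                                     three_end = numeric(0),
                                     five_end = numeric(0),
                                     untemplated = character(0))))
    }
    types <- sample(names(mix), n, replace = TRUE, prob = mix)
    clones <- character(n); rows <- vector("list", n)
    for (i in seq_len(n)) {
      type <- types[i]
      if (type == "crt5") {
        aj <- min(max(a + jitter(), 2L * 12L), L)   # keep anchors feasible
        ut <- tail_a()
        x <- max(1L, aj - rl + 1L)
        m <- min(rl, aj)
        clone <- paste0(substr(tx, x, aj), ut, substr(tx, 1L, m))
        rows[[i]] <- data.frame(type = type, method = "cRT-PCR",
                                three_end = aj, five_end = 1,
                                untemplated = ut, stringsAsFactors = FALSE)
      } else if (type == "crt3") {
        bj <- min(max(b + jitter(), 1L), L - 2L * 12L)
        ut <- tail_a()
        y <- max(bj, L - rl + 1L)
        z <- min(L, bj + rl - 1L)
        clone <- paste0(substr(tx, y, L), ut, substr(tx, bj, z))
        rows[[i]] <- data.frame(type = type, method = "cRT-PCR",
                                three_end = L, five_end = bj,
                                untemplated = ut, stringsAsFactors = FALSE)
      } else {
        bj <- min(max(b + jitter(), 1L), L - 2L * 12L)
        z <- min(L, bj + rl - 1L)
        clone <- paste0("GGG", substr(tx, bj, z))
        rows[[i]] <- data.frame(type = type, method = "RACE",
                                three_end = NA_real_, five_end = bj,
                                untemplated = "", stringsAsFactors = FALSE)
      }
      clones[i] <- addErrors(clone)
    }
    names(clones) <- sprintf("clone%04d", seq_len(n))
    truth <- do.call(rbind, rows)
    truth$clone <- names(clones)
    list(clones = Biostrings::RNAStringSet(clones), truth = truth)
  })
}

#' Simulate a replicate count matrix with planted fold changes
#'
#' Draws negative-binomial counts with variance `mu + alpha * mu^2`. Sample
#' means are `mean_t * foldchange_t` in the second condition and `mean_t` in
#' the first, both scaled by a per-sample library scalar.
#'
#' @param config list with `means` (named per-transcript baseline means),
#'   `dispersion` (alpha > 0, or 0 for the Poisson limit), `replicates`
#'   (length-2, replicates per condition), `fold_changes` (named; transcripts
#'   absent default to 1), `conditions` (two condition names) and optional
#'   `lib_scalars` (length `sum(replicates)`; default drawn log-normal,
#'   sdlog 0.15).
#' @param seed integer seed.
#' @return list with `se` (a `SummarizedExperiment` as from [countMatrix()])
#'   and `truth` (means, fold changes and library scalars used).
#' @export
simulateCounts <- function(config, seed = 1L) {
  mu <- config$means
  if (any(mu <= 0)) stop("transcript means must be positive", call. = FALSE)
  alpha <- config$dispersion
  if (is.null(alpha)) alpha <- 0.05
  if (alpha < 0) stop("dispersion must be >= 0", call. = FALSE)
  reps <- config$replicates
  if (is.null(reps)) reps <- c(4L, 4L)
  conds <- config$conditions
  if (is.null(conds)) conds <- c("WT", "modified")
  fc <- stats::setNames(rep(1, length(mu)), names(mu))
  if (!is.null(config$fold_changes))
    fc[names(config$fold_changes)] <- unlist(config$fold_changes)

  .withSeed(seed, {
    nS <- sum(reps)
    lib <- config$lib_scalars
    if (is.null(lib)) lib <- exp(stats::rnorm(nS, 0, 0.15))
    condition <- rep(conds, reps)
    sampleNames <- paste0(rep(conds, reps), "_",
                          unlist(lapply(reps, seq_len)))
    m <- matrix(0L, nrow = length(mu), ncol = nS,
                dimnames = list(names(mu), sampleNames))
    for (s in seq_len(nS)) {
      mus <- if (condition[s] == conds[2L]) mu * fc * lib[s] else mu * lib[s]
      m[, s] <- if (alpha == 0) stats::rpois(length(mus), mus)
                else stats::rnbinom(length(mus), mu = mus, size = 1 / alpha)
    }
    se <- countMatrix(m, factor(condition, levels = conds))
    list(se = se,
         truth = list(means = mu, fold_changes = fc, lib_scalars = lib,
                      dispersion = alpha))
  })
}

#' Default count scenario mirroring the study shape
#'
#' Thirty-three mitochondrial transcripts, four replicates per genotype, and
#' a single transcript (nad6) planted at fold change 0.25 — the "reduced
#' about fourfold" effect — with NB dispersion 0.05. Shipped as a YAML
#' config under `extdata`.
#'
#' @return a config list for [simulateCounts()].
#' @export
defaultCountScenario <- function() {
  path <- system.file("extdata", "default_scenario.yaml",
                      package = "pprtarget", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  cfg$means <- unlist(cfg$means)
  cfg$fold_changes <- unlist(cfg$fold_changes)
  cfg$replicates <- as.integer(unlist(cfg$replicates))
  cfg$conditions <- as.character(unlist(cfg$conditions))
  cfg
}
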