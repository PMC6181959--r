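# Minimal per-transcript fold-change estimation on replicate count matrices:
# median-of-ratios normalization and a pseudocount log2 ratio with a
# percentile bootstrap CI.

#' Assemble a count matrix with a condition design
#'
#' @param counts integer matrix, transcripts x samples (row and column names
#'   required).
#' @param conditions factor/character of length `ncol(counts)` assigning each
#'   sample to one of exactly two conditions, each with at least two
#'   replicates.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts` and `colData$condition`.
#' @export
countMatrix <- function(counts, conditions) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (length(conditions) != ncol(counts))
    stop("one condition per sample required", call. = FALSE)
  conditions <- factor(conditions)
  if (nlevels(conditions) != 2L)
    stop("exactly two conditions required", call. = FALSE)
  if (any(table(conditions) < 2L))
    stop("each condition needs at least two replicates", call. = FALSE)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(condition = conditions,
                                   row.names = colnames(counts)))
}

#' @keywords internal
#' @noRd
.getCounts <- function(x) {
  if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts")
  else as.matrix(x)
}

#' Median-of-ratios normalization
#'
#' Size factor of a sample = median over reference transcripts of the ratio
#' of its count to the transcript's geometric mean across samples; the
#' reference set is the transcripts with nonzero counts in every sample.
#' Factors are rescaled to median 1 (so a sample with exactly doubled
#' counts gets size factor 2 against an unchanged majority); the common
#' rescaling cancels from any between-sample ratio. Normalized counts are
#' raw counts divided by the sample's size factor.
#'
#' @param counts a matrix or a `SummarizedExperiment` carrying a `counts`
#'   assay.
#' @return list with `sizeFactors` (named numeric) and `normalized` (matrix).
#' @export
normalizeCounts <- function(counts) {
  m <- .getCounts(counts)
  ref <- rowSums(m == 0) == 0L
  if (!any(ref))
    stop("no reference transcript with nonzero counts in all samples",
         call. = FALSE)
  logGeo <- rowMeans(log(m[ref, , drop = FALSE]))
  sf <- apply(m[ref, , drop = FALSE], 2L, function(col)
    exp(stats::median(log(col) - logGeo)))
  sf <- sf / stats::median(sf)
  list(sizeFactors = sf, normalized = sweep(m, 2L, sf, "/"))
}

#' Per-transcript log2 fold changes with bootstrap CIs
#'
#' Estimates, for every transcript, `log2((mean2 + pc) / (mean1 + pc))`
#' where the means are over normalized counts of replicates in each
#' condition (`cond2` relative to `cond1`, the first factor level by
#' default), with a seeded percentile bootstrap over replicates.
#'
#' @param x a `SummarizedExperiment` from [countMatrix()], or a matrix (then
#'   supply `conditions`).
#' @param conditions condition factor (ignored when `x` carries one).
#' @param pseudocount added to both means before the ratio (default 0.5).
#' @param nBoot bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param normalize apply [normalizeCounts()] first (default `TRUE`).
#' @return `DataFrame` with columns `transcript`, `log2FC`, `ci_lo`,
#'   `ci_hi` (2.5/97.5 percentiles).
#' @export
log2FoldChanges <- function(x, conditions = NULL, pseudocount = 0.5,
                            nBoot = 1000L, seed = 1L, normalize = TRUE) {
  m <- .getCounts(x)
  if (is(x, "SummarizedExperiment"))
    conditions <- SummarizedExperiment::colData(x)$condition
  if (is.null(conditions))
    stop("conditions are required", call. = FALSE)
  conditions <- factor(conditions)
  if (nlevels(conditions) != 2L)
    stop("exactly two conditions required", call. = FALSE)
  if (any(table(conditions) < 1L))
    stop("a condition has zero replicates", call. = FALSE)
  if (normalize) m <- normalizeCounts(m)$normalized
  i1 <- which(conditions == levels(conditions)[1L])
  i2 <- which(conditions == levels(conditions)[2L])

  est <- function(m1, m2) {
    log2((rowMeans(m2) + pseudocount) / (rowMeans(m1) + pseudocount))
  }
  lfc <- est(m[, i1, drop = FALSE], m[, i2, drop = FALSE])
  ci <- .withSeed(seed, {
    boots <- replicate(nBoot, {
      b1 <- sample(i1, length(i1), replace = TRUE)
      b2 <- sample(i2, length(i2), replace = TRUE)
      est(m[, b1, drop = FALSE], m[, b2, drop = FALSE])
    })
    if (is.null(dim(boots))) boots <- matrix(boots, nrow = 1L)
    apply(boots, 1L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  })
  S4Vectors::DataFrame(transcript = rownames(m), log2FC = unname(lfc),
                       ci_lo = ci[1L, ], ci_hi = ci[2L, ])
}
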