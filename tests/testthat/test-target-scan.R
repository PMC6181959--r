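tbl <- loadCodeTable()

test_that("countDifferences is a Hamming distance with T/U equivalence", {
  expect_equal(countDifferences("ACGU", "ACGU"), 0)
  expect_equal(countDifferences("ACGU", "ACGA"), 1)
  expect_equal(countDifferences("acgt", "ACGU"), 0)
  expect_equal(countDifferences("CCCC", "UUUU", cuLenient = TRUE), 2)
  expect_error(countDifferences("ACG", "ACGU"), "unequal")
})

test_that("findNearMatches reports overlapping and vacuous-threshold hits", {
  hits <- findNearMatches("AAAA", c(s = "AAAAA"), maxDiff = 0)
  expect_equal(hits$start, c(1L, 2L))
  expect_equal(hits$end, c(4L, 5L))

  all <- findNearMatches("ACGU", c(s = "GGGGGGG"), maxDiff = 4)
  expect_equal(nrow(all), 4L)  # every window when threshold is vacuous
  expect_error(findNearMatches("", c(s = "ACGU"), 0), "non-empty")
})

test_that("exact near-match hits equal substring occurrences", {
  set.seed(101)
  for (i in 1:20) {
    s <- rand_rna(300)
    site <- substr(s, 120, 131)
    hits <- findNearMatches(site, c(x = s), maxDiff = 0)
    occ <- gregexpr(site, s, fixed = TRUE)[[1L]]
    expect_equal(hits$start, as.integer(occ))
  }
})

test_that("iupacSearch honours IUPAC classes and mismatch budgets", {
  expect_equal(nrow(iupacSearch("N", c(s = "A"), 0)), 1L)
  h <- iupacSearch("RY", c(s = "GACU"), 0)
  expect_equal(h$start, 2L)
  expect_equal(h$window, "AC")
  expect_error(iupacSearch("RZ", c(s = "ACGU"), 0), "IUPAC")

  set.seed(7)
  s <- rand_rna(400)
  # a pattern of all N matches every window
  expect_equal(nrow(iupacSearch(strrep("N", 8), c(x = s), 0)), 400 - 8 + 1)
  # hits at stricter budgets are subsets of looser ones
  h0 <- iupacSearch("NAAAURCGACCUNUCY", c(x = s), 0)
  h1 <- iupacSearch("NAAAURCGACCUNUCY", c(x = s), 1)
  key <- function(h) paste(h$seq_id, h$start, h$strand)
  expect_true(all(key(h0) %in% key(h1)))
})

test_that("planted sites are recovered uniquely by both search modes", {
  cfg <- list(n_transcripts = 8, length_range = c(500, 1500),
              planted_sites = data.frame(
                site = "AAAAUACGACCUAUCC", transcript = 3, position = 200,
                n_mutations = 0))
  sim <- simulateTranscriptome(cfg, seed = 31)
  hits <- findNearMatches("AAAAUACGACCUAUCC", sim$seqs, maxDiff = 0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$seq_id, sim$truth$transcript)
  expect_equal(hits$start, 200L)
  p <- iupacSearch("NAAAURCGACCUNUCY", sim$seqs, 0)
  expect_equal(nrow(p), 1L)
  expect_equal(p$start, 200L)
})

test_that("buildOfftargetPattern applies the unanimity/class/conflict rules", {
  # identical natural targets reproduce the design target verbatim
  p0 <- buildOfftargetPattern("ACGU", c("ACGU", "ACGU"))
  expect_equal(p0@pattern, "ACGU")
  # design G with natural A at one position -> R; A vs C -> N
  p1 <- buildOfftargetPattern("GA", c("AA", "GA"))
  expect_equal(p1@pattern, "RA")
  p2 <- buildOfftargetPattern("AU", c("CU"))
  expect_equal(substr(p2@pattern, 1, 1), "N")
  # pyrimidine class
  p3 <- buildOfftargetPattern("CA", c("UA"))
  expect_equal(p3@pattern, "YA")
  expect_error(buildOfftargetPattern("ACG", c("AC")), "length")
})

test_that("off-target patterns never exclude the natural targets", {
  set.seed(55)
  for (i in 1:50) {
    k <- sample(8:20, 1)
    design <- rand_rna(k)
    nat <- vapply(1:3, function(j) {
      chars <- strsplit(design, "")[[1L]]
      flip <- sample(k, sample(0:4, 1))
      chars[flip] <- vapply(chars[flip], function(b)
        sample(setdiff(c("A", "C", "G", "U"), b), 1), character(1))
      paste(chars, collapse = "")
    }, character(1))
    pat <- buildOfftargetPattern(design, nat)
    for (t in c(design, nat)) {
      h <- iupacSearch(pat, c(t = t), 0)
      expect_equal(nrow(h), 1L)
    }
  }
})

test_that("scanArray finds a planted all-perfect site as the unique top hit", {
  set.seed(77)
  arr <- rand_array(16)
  target <- iupacString(predictRecognition(arr, tbl), "strict")
  cfg <- list(n_transcripts = 5, length_range = c(800, 1200),
              planted_sites = data.frame(site = target, transcript = 2,
                                         position = 400, n_mutations = 0))
  sim <- simulateTranscriptome(cfg, seed = 13)
  hits <- scanArray(arr, sim$seqs, tbl, minScore = 16)
  top <- hits[1L, ]
  expect_equal(top$start, 400L)
  expect_equal(top$seq_id, sim$truth$transcript)
  expect_equal(top$score, 16)
  # an unreachable threshold returns nothing
  expect_equal(nrow(scanArray(arr, sim$seqs, tbl, minScore = 17)), 0L)
})

test_that("all four search operations agree with the brute-force oracle", {
  set.seed(2024)
  n_cases <- 100
  for (i in seq_len(n_cases)) {
    nseq <- sample(1:3, 1)
    seqs <- setNames(vapply(seq_len(nseq),
                            function(j) rand_rna(sample(80:400, 1)),
                            character(1)),
                     paste0("s", seq_len(nseq)))
    both <- i %% 2 == 0

    site <- rand_rna(sample(5:9, 1))
    md <- sample(0:2, 1)
    expect_same_hits(findNearMatches(site, seqs, md, bothStrands = both),
                     oracle_near_matches(site, seqs, md, both), "mismatches")

    pat <- paste(sample(c("A", "C", "G", "U", "R", "Y", "N", "S", "W", "B"),
                        sample(4:8, 1), replace = TRUE), collapse = "")
    mm <- sample(0:1, 1)
    expect_same_hits(iupacSearch(pat, seqs, mm, bothStrands = both),
                     oracle_iupac(pat, seqs, mm, both), "mismatches")

    if (i <= 30) {  # array scans are the slow oracle; 30 cases suffice
      arr <- rand_array(sample(5:10, 1))
      ms <- length(arr) - sample(0:2, 1)
      expect_same_hits(scanArray(arr, seqs, tbl, ms, bothStrands = both),
                       oracle_scan(arr, seqs, tbl, ms, both), "score")
    }

    a <- rand_rna(30); b <- rand_rna(30)
    expect_equal(countDifferences(a, b), hamming_chr(a, b))
  }
})

test_that("minus-strand hits report forward-strand coordinates", {
  s <- c(x = paste0(rand_rna(40), revcomp_rna("ACGGAUCCGA"), rand_rna(40)))
  set.seed(3)
  hits <- findNearMatches("ACGGAUCCGA", s, 0, bothStrands = TRUE)
  minus <- hits[hits$strand == "-", ]
  expect_equal(nrow(minus), 1L)
  expect_equal(minus$start, 41L)
  expect_equal(minus$end, 50L)
  expect_equal(minus$window, "ACGGAUCCGA")
})
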