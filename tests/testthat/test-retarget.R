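tbl <- loadCodeTable()

test_that("already-perfect targets need no edits; single changes edit once", {
  arr <- pprArray("toy", c("T", "T"), c("D", "N"))  # recognizes GA
  d0 <- designRetarget(arr, "GA", tbl)
  expect_equal(nrow(designEdits(d0)), 0L)
  expect_equal(motifs(designedArray(d0)), motifs(arr))

  # (T,D) recognizing G edited toward A must pick (T,N): shares res5 T
  d1 <- designRetarget(arr, "AA", tbl)
  ed <- designEdits(d1)
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$motif_index, 1L)
  expect_equal(c(ed$new_res5, ed$new_res35), c("T", "N"))
})

test_that("edit counts equal target Hamming distance in the all-perfect regime", {
  set.seed(909)
  for (i in 1:40) {
    n <- sample(10:20, 1)
    arr <- rand_array(n)
    old <- iupacString(predictRecognition(arr, tbl), "strict")
    chars <- strsplit(old, "")[[1L]]
    k <- sample(0:n, 1)
    flip <- sample(n, k)
    chars[flip] <- vapply(chars[flip], function(b)
      sample(setdiff(c("A", "C", "G", "U"), b), 1), character(1))
    newTarget <- paste(chars, collapse = "")
    d <- designRetarget(arr, newTarget, tbl)
    expect_equal(nrow(designEdits(d)), hamming_chr(old, newTarget))
  }
})

test_that("recognition -> design -> recognition round trip is exact", {
  set.seed(4242)
  for (i in 1:1000) {
    n <- sample(10:20, 1)
    parent <- rand_array(n)
    target <- rand_rna(n)
    d <- designRetarget(parent, target, tbl)
    expect_identical(
      iupacString(predictRecognition(designedArray(d), tbl), "strict"),
      target)
  }
})

test_that("partial positions are edited by default but kept on request", {
  arr <- pprArray("nn", "N", "N")  # C primary, U secondary
  dDefault <- designRetarget(arr, "U", tbl)
  expect_equal(nrow(designEdits(dDefault)), 1L)
  expect_equal(designEdits(dDefault)$new_res35, "D")  # (N,D) shares res5 N
  dKeep <- designRetarget(arr, "U", tbl, keepPartial = TRUE)
  expect_equal(nrow(designEdits(dKeep)), 0L)
})

test_that("unreachable target bases raise an error naming the position", {
  noU <- new("CodeTable",
             entries = list("T,N" = list(primary = "A", secondary = character(0))),
             defaultPolicy = "partial-all")
  arr <- pprArray("a", c("T", "T"), c("N", "N"))
  expect_error(designRetarget(arr, "AU", noU), "position\\(s\\) 2")
})

test_that("design report degrades parent-target matches consistently", {
  set.seed(31415)
  for (i in 1:30) {
    n <- sample(10:16, 1)
    parent <- rand_array(n)
    natural <- iupacString(predictRecognition(parent, tbl), "strict")
    target <- rand_rna(n)
    d <- designRetarget(parent, target, tbl,
                        naturalTargets = c(nat = natural))
    rep <- designReport(d)$nat
    # brute-force recomputation of the designed array on the natural target
    recomputed <- scoreAlignment(designedArray(d), natural, tbl)@classes
    expect_equal(rep, recomputed)
    mism <- sum(recomputed == "MISMATCH")
    partial <- sum(recomputed == "PARTIAL")
    expect_gte(mism, hamming_chr(target, natural) - partial)
  }
})

test_that("emitProtein substitutes only the edited specificity residues", {
  set.seed(88)
  prot <- local({
    aa <- sample(c("A", "L", "G", "K", "R", "E"), 70, replace = TRUE)
    aa[c(5, 35)] <- c("T", "D"); aa[c(40, 70)] <- c("T", "N")
    paste(aa, collapse = "")
  })
  arr <- pprArray("p2", c("T", "T"), c("D", "N"), proteinSeq = prot)

  d0 <- designRetarget(arr, "GA", tbl)
  expect_identical(emitProtein(prot, d0), prot)

  d1 <- designRetarget(arr, "AA", tbl)
  out <- emitProtein(prot, d1)
  expect_equal(nchar(out), nchar(prot))
  diffs <- which(strsplit(out, "")[[1L]] != strsplit(prot, "")[[1L]])
  expect_true(length(diffs) <= 2L)           # one edit touches at most 2 aa
  expect_true(all(diffs %in% c(5L, 35L)))
  expect_equal(substr(out, 35, 35), "N")     # (T,D) -> (T,N): only pos 35 moves
  expect_equal(length(diffs), 1L)

  # spans beyond the protein are rejected
  short <- substr(prot, 1, 40)
  expect_error(emitProtein(short, d1_bad <- designRetarget(
    pprArray("p2", c("T", "T"), c("D", "N")), "AG", tbl)), "span")
})

test_that("emitProtein changes at most two residues per edit across designs", {
  set.seed(515)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    picks <- sample(length(CANONICAL_PAIRS), n, replace = TRUE)
    res5 <- vapply(picks, function(j) CANONICAL_PAIRS[[j]][1], character(1))
    res35 <- vapply(picks, function(j) CANONICAL_PAIRS[[j]][2], character(1))
    aa <- sample(c("A", "L", "G", "K"), 35 * n, replace = TRUE)
    for (j in seq_len(n)) {
      aa[35 * (j - 1) + 5] <- res5[j]; aa[35 * (j - 1) + 35] <- res35[j]
    }
    prot <- paste(aa, collapse = "")
    arr <- pprArray("x", res5, res35, proteinSeq = prot)
    d <- designRetarget(arr, rand_rna(n), tbl)
    out <- emitProtein(prot, d)
    ndiff <- sum(strsplit(out, "")[[1L]] != strsplit(prot, "")[[1L]])
    expect_lte(ndiff, 2L * nrow(designEdits(d)))
  }
})
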