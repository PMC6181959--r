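test_that("transcript models do coordinate arithmetic on both strands", {
  plus <- transcriptModel("t", "g", 1001, "+", 100, 300, 50)
  expect_equal(transcriptLength(plus), 450)
  expect_equal(transcriptToGenome(plus, 1), 1001)
  expect_equal(genomeToTranscript(plus, 1450), 450)
  minus <- transcriptModel("t", "g", 5000, "-", 100, 300, 50)
  expect_equal(transcriptToGenome(minus, 1), 5000)
  expect_equal(transcriptToGenome(minus, 450), 4551)
  expect_equal(genomeToTranscript(minus, 4551), 450)
  expect_error(genomeToTranscript(plus, 100), "outside")
  expect_error(transcriptModel("t", "g", 1, "*", 1, 1, 1))
})

test_that("cleavage events enforce ordering and expose the gap", {
  ev <- cleavageEvent(100, 134)
  expect_equal(gapLength(ev), 33)
  expect_error(cleavageEvent(100, 100))
  expect_equal(unname(cleavageDistances(134, 80, 95)), c(54, 39))
})

test_that("intact circularized molecules decompose to (L, 1, '')", {
  set.seed(6)
  tx <- rand_rna(200)
  clone <- paste0(substr(tx, 161, 200), substr(tx, 1, 30))
  d <- decomposeClone(clone, tx)
  expect_equal(d$threeEnd, 200)
  expect_equal(d$fiveEnd, 1)
  expect_equal(d$untemplated, "")
})

test_that("untemplated junction bases are returned as the insert", {
  set.seed(9)
  tx <- rand_rna(300)
  # 5' product ends at 140 with an untemplated A; pick a junction where the
  # A cannot be absorbed into either anchor
  a <- 140
  while (substr(tx, a + 1, a + 1) == "A") a <- a + 1
  clone <- paste0(substr(tx, a - 60, a), "A", substr(tx, 1, 50))
  d <- decomposeClone(clone, tx)
  expect_equal(d$threeEnd, a)
  expect_equal(d$fiveEnd, 1)
  expect_equal(d$untemplated, "A")

  expect_error(decomposeClone(substr(tx, 1, 20), tx), "unmappable")
  expect_error(decomposeClone(paste(rep("A", 60), collapse = ""), tx),
               "unmappable")
})

test_that("clone decomposition is exact across cleavage positions", {
  set.seed(12)
  tx <- rand_rna(260)
  L <- nchar(tx)
  for (a in seq(14, L - 14, by = 7)) {
    # 5'-product clone: suffix anchor is the transcript start, never ambiguous
    clone5 <- paste0(substr(tx, max(1, a - 50), a), substr(tx, 1, 40))
    d5 <- decomposeClone(clone5, tx)
    expect_equal(d5$threeEnd, a)
    expect_equal(d5$fiveEnd, 1)
  }
  for (b in seq(14, L - 30, by = 7)) {
    clone3 <- paste0(substr(tx, L - 40, L), substr(tx, b, min(L, b + 50)))
    d3 <- decomposeClone(clone3, tx)
    if (substr(tx, b - 1, b - 1) != substr(tx, L, L)) {
      expect_equal(d3$threeEnd, L)
      expect_equal(d3$fiveEnd, b)   # unambiguous junction: exact
    } else {
      # junction bases credited to the 5' anchor shift both ends in step
      expect_lte(d3$fiveEnd, b)
      expect_equal(L - d3$threeEnd, b - d3$fiveEnd)
    }
  }
})

test_that("RACE clones map the 5'-most represented base, trimming adapters", {
  set.seed(21)
  tx <- rand_rna(300)
  p <- 120
  expect_equal(mapRaceEnd(substr(tx, p, 300), tx), p)
  adapterSafe <- p
  while (substr(tx, adapterSafe - 1, adapterSafe - 1) == "G")
    adapterSafe <- adapterSafe + 1
  expect_equal(mapRaceEnd(paste0("GGG", substr(tx, adapterSafe, 300)), tx),
               adapterSafe)
  expect_error(mapRaceEnd("ACGUACGUACGUACGU", tx), "unmappable")
})

test_that("summarizeEnds tallies per coordinate/method and flags the window", {
  d <- data.frame(three_end = c(100, 100, 100, NA),
                  five_end = c(1, 1, 1, 140),
                  method = c("cRT-PCR", "cRT-PCR", "cRT-PCR", "RACE"))
  em <- summarizeEnds(d, window = c(90, 150))
  tab <- endCounts(em)
  expect_equal(tab$count[tab$coord == 100 & tab$end_class == "3prime"], 3L)
  expect_equal(tab$count[tab$coord == 140 & tab$end_class == "5prime"], 1L)
  expect_false(any(tab$in_window[tab$coord == 1]))
  expect_true(all(tab$in_window[tab$coord %in% c(100, 140)]))
  # counts per class sum to the mappable clones carrying that end
  expect_equal(sum(tab$count[tab$end_class == "3prime"]), 3L)
  expect_equal(sum(tab$count[tab$end_class == "5prime"]), 4L)

  empty <- summarizeEnds(d[0, ], window = c(1, 10))
  expect_equal(nrow(endCounts(empty)), 0L)
})

test_that("inferCleavage picks modal ends and reports the gap", {
  d <- data.frame(three_end = c(200, 200, 201), five_end = c(234, 234, 234),
                  method = "cRT-PCR")
  ev <- inferCleavage(summarizeEnds(d, c(150, 300)))
  expect_equal(ev@fiveEnd, 200)
  expect_equal(ev@threeStart, 234)
  expect_equal(gapLength(ev), 33)

  only5 <- data.frame(three_end = NA, five_end = 234, method = "RACE")
  expect_error(inferCleavage(summarizeEnds(only5, c(150, 300))),
               "no in-window 3prime")

  tie <- data.frame(three_end = c(200, 201), five_end = c(234, 234),
                    method = "cRT-PCR")
  expect_warning(evt <- inferCleavage(summarizeEnds(tie, c(150, 300))), "tie")
  expect_equal(evt@fiveEnd, 200)  # tie resolved toward the larger gap
})

test_that("fragment predictions conserve total transcript length", {
  nad6 <- transcriptModel("nad6", "mt", 164694, "+", 179, 601, 0)
  expect_equal(unname(predictFragments(nad6, cleavageEvent(165236, 165269))),
               c(543, 205, 780))
  toy <- transcriptModel("toy", "g", 1, "+", 20, 80, 0)
  fr <- predictFragments(toy, cleavageEvent(50, 51))
  expect_equal(unname(fr), c(50, 50, 100))
  set.seed(77)
  for (i in 1:30) {
    a <- sample(10:80, 1); b <- sample((a + 1):95, 1)
    fr <- predictFragments(toy, cleavageEvent(a, b))
    expect_equal(fr[["five_prime_fragment"]] + (b - a - 1) +
                   fr[["three_prime_fragment"]], 100)
  }
  expect_error(predictFragments(toy, cleavageEvent(50, 200)), "outside")
})

test_that("simulated clone sets round-trip to the planted event", {
  set.seed(5)
  tx <- rand_rna(700)
  # choose a junction-safe 3'-product start so exact recovery is well defined
  b <- 377
  while (substr(tx, b - 1, b - 1) %in% c(substr(tx, 700, 700), "G"))
    b <- b + 1
  ev <- cleavageEvent(340, b)
  sim <- simulateClones(tx, ev, 120,
                        config = list(jitter_prob = 0, untemplated_prob = 0,
                                      error_rate = 0),
                        seed = 77)
  dec <- lapply(seq_len(120), function(i) {
    meth <- sim$truth$method[i]
    if (meth == "RACE")
      data.frame(three_end = NA, five_end =
                   mapRaceEnd(as.character(sim$clones[[i]]), tx),
                 method = meth)
    else {
      d <- decomposeClone(as.character(sim$clones[[i]]), tx)
      data.frame(three_end = d$threeEnd, five_end = d$fiveEnd, method = meth)
    }
  })
  em <- summarizeEnds(do.call(rbind, dec), window = c(300, 420))
  got <- inferCleavage(em)
  expect_equal(got@fiveEnd, 340)
  expect_equal(got@threeStart, b)
  expect_equal(gapLength(got), b - 340 - 1)
})
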