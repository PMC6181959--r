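test_that("generators are byte-identical under a fixed seed", {
  cfg <- list(n_transcripts = 5, length_range = c(200, 400),
              planted_sites = data.frame(site = "ACGUACGUACGU",
                                         transcript = 1, position = 50,
                                         n_mutations = 2))
  a <- simulateTranscriptome(cfg, seed = 99)
  b <- simulateTranscriptome(cfg, seed = 99)
  expect_identical(as.character(a$seqs), as.character(b$seqs))
  expect_identical(a$truth, b$truth)
  c <- simulateTranscriptome(cfg, seed = 100)
  expect_false(identical(as.character(a$seqs), as.character(c$seqs)))

  cnt1 <- simulateCounts(defaultCountScenario(), seed = 5)
  cnt2 <- simulateCounts(defaultCountScenario(), seed = 5)
  expect_identical(SummarizedExperiment::assay(cnt1$se),
                   SummarizedExperiment::assay(cnt2$se))

  ev <- cleavageEvent(100, 140)
  set.seed(1); tx <- rand_rna(400)
  cl1 <- simulateClones(tx, ev, 30, seed = 3)
  cl2 <- simulateClones(tx, ev, 30, seed = 3)
  expect_identical(as.character(cl1$clones), as.character(cl2$clones))
})

test_that("planted sites carry exactly the requested mutations", {
  cfg <- list(n_transcripts = 4, length_range = c(300, 500),
              planted_sites = data.frame(
                site = c("AAAAUACGACCUAUCC", "AAAAUACGACCUAUCC"),
                transcript = c(1, 3), position = c(40, 100),
                n_mutations = c(0, 3)))
  sim <- simulateTranscriptome(cfg, seed = 17)
  tr <- sim$truth
  expect_equal(countDifferences(tr$site[1], tr$planted[1]), 0)
  expect_equal(countDifferences(tr$site[2], tr$planted[2]), 3)
  # the planted copies are present at the recorded positions
  for (i in 1:2) {
    s <- as.character(sim$seqs[[tr$transcript[i]]])
    expect_equal(substr(s, tr$position[i], tr$position[i] + 15),
                 tr$planted[i])
  }
  bad <- list(n_transcripts = 2, length_range = c(30, 40),
              planted_sites = data.frame(site = strrep("A", 50),
                                         transcript = 1, position = 1,
                                         n_mutations = 0))
  expect_error(simulateTranscriptome(bad, seed = 1), "bounds")
})

test_that("clone generator realizes the event, tails and empty sets", {
  set.seed(2); tx <- rand_rna(500)
  b <- 300
  while (substr(tx, b - 1, b - 1) %in% c(substr(tx, 500, 500), "G", "A"))
    b <- b + 1
  a <- 250   # tails at the 5'-product end must not be template-absorbable
  while (substr(tx, a + 1, a + 1) == "A") a <- a - 1
  ev <- cleavageEvent(a, b)

  empty <- simulateClones(tx, ev, 0, seed = 1)
  expect_equal(length(empty$clones), 0L)

  # untemplated probability 1: every cRT decomposition reports adenosines
  sim <- simulateClones(tx, ev, 40,
                        config = list(jitter_prob = 0, error_rate = 0,
                                      untemplated_prob = 1,
                                      mix = c(crt5 = 0.5, crt3 = 0.5)),
                        seed = 9)
  for (i in seq_len(40)) {
    d <- decomposeClone(as.character(sim$clones[[i]]), tx)
    expect_match(d$untemplated, "^A+$")
  }
  expect_true(all(nchar(sim$truth$untemplated) %in% 1:3))
})

test_that("NB counts approach their means in the Poisson limit", {
  mu <- c(t1 = 500, t2 = 2000)
  cfg <- list(means = mu, dispersion = 0, replicates = c(500, 500),
              conditions = c("A", "B"), lib_scalars = rep(1, 1000))
  sim <- simulateCounts(cfg, seed = 33)
  m <- SummarizedExperiment::assay(sim$se)
  expect_lt(abs(mean(m["t1", ]) - 500) / 500, 0.05)
  expect_lt(abs(mean(m["t2", ]) - 2000) / 2000, 0.05)
  expect_error(simulateCounts(list(means = c(t1 = -5)), seed = 1),
               "positive")
})

test_that("fold change 1 everywhere centres log2 ratios on zero", {
  cfg <- defaultCountScenario()
  cfg$fold_changes <- NULL
  sim <- simulateCounts(cfg, seed = 21)
  lfc <- log2FoldChanges(sim$se, nBoot = 10, seed = 21)
  expect_lt(abs(mean(lfc$log2FC)), 0.1)
})

test_that("the synthetic reference genome is fixed and self-consistent", {
  ref <- syntheticMitoGenome()
  expect_equal(unname(nchar(ref$genome)), 367808L)
  expect_equal(length(ref$transcripts), 33L)
  # every transcript model extracts to its stated mature length
  for (nm in names(ref$models)) {
    expect_equal(nchar(as.character(ref$transcripts[[nm]])),
                 transcriptLength(ref$models[[nm]]))
  }
  # planted sites are present where the truth table says
  for (i in seq_len(nrow(ref$sites))) {
    s <- ref$sites[i, ]
    txSeq <- as.character(ref$transcripts[[s$transcript]])
    expect_equal(substr(txSeq, s$tx_start, s$tx_end), s$seq)
  }
  # the design site sits at CDS +349 of nad6 (= genome 165,221)
  nad6 <- ref$models$nad6
  expect_equal(transcriptToGenome(nad6, nad6@utr5 + 349), 165221)
  expect_equal(transcriptToGenome(nad6, 1), 164694)
})
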