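Package: pprtarget
Title: Retargeting Pentatricopeptide Repeat Proteins and Mapping Induced RNA Cleavage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models P-class pentatricopeptide repeat (PPR) protein arrays and
    the amino-acid to RNA-base recognition code, predicts recognition
    sequences, scans transcriptomes and organellar genomes for candidate
    binding sites (array scoring, mismatch-tolerant literal search and
    degenerate IUPAC pattern search), designs the specificity-residue edits
    that re-target an array to a new RNA site, decomposes circular RT-PCR and
    5'-RACE clones into transcript 5'/3' ends to map cleavage events, and
    estimates per-transcript fold changes from replicate count matrices.
    Seeded simulators generate transcriptomes with planted binding sites,
    cleaved-transcript clone sets and negative-binomial count matrices so the
    whole pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
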