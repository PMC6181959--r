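---
title: "Retargeting PPR proteins and mapping induced RNA cleavage"
author: "pprtarget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retargeting PPR proteins and mapping induced RNA cleavage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pprtarget)
```

## The problem

Plant mitochondrial genes cannot be knocked out by transformation, but the
expression of a chosen mitochondrial mRNA can be blocked by re-directing a
natural RNA-binding protein at it. P-class pentatricopeptide repeat (PPR)
proteins bind RNA in a modular, largely predictable way: each ~35-amino-acid
motif contacts one nucleotide, and the identity of two "specificity"
residues (motif positions 5 and 35) largely determines which base the motif
prefers — the *PPR code*. Restorer-of-fertility-like (RFL) proteins such as
RNA PROCESSING FACTOR 2 (RPF2, 16 motifs, natural targets in the *cox3* and
*nad9* 5'-UTRs) additionally trigger cleavage of the transcripts they bind.
Swapping the specificity residues of such a protein therefore converts it
into a programmable mRNA-cleaving factor, here modelled on the re-direction
of an RPF2-like scaffold against a site inside the *nad6* coding sequence.

`pprtarget` implements the computational side of that experiment as a
reusable, tested pipeline:

1. **PPR code model** — motif arrays, the residue-pair-to-base code table,
   three-class match calls (perfect / partial / mismatch), recognition
   sequences and window scoring.
2. **Target search** — sliding-window array scans, mismatch-tolerant search
   for a literal site, and degenerate IUPAC pattern search for off-target
   audits.
3. **Re-design** — the minimal set of specificity-residue edits converting a
   parent array into a perfect predicted binder of a new site, plus the
   modified protein sequence.
4. **Cleavage mapping** — decomposition of circular RT-PCR (cRT-PCR)
   junction clones and 5'-RACE clones into transcript 5'/3' ends, end maps,
   cleavage-event inference and northern fragment-size prediction.
5. **Fold-change estimation** — median-of-ratios normalization and a
   pseudocount log2 ratio with bootstrap CIs on replicate count matrices.
6. **Simulation** — seeded generators for transcriptomes with planted
   sites, clone sets realizing a cleavage model, and negative-binomial
   count matrices with planted fold changes.

## The match model and its parameters

The shipped code table contains the canonical P-class combinations:
(T,N)→A, (T,D)→G, (N,D)→U, (N,N)→C with U as a partial match, and
(S,N)→A, (S,D)→G. A base in a pair's primary set is a `PERFECT` match, in
its secondary set `PARTIAL`, otherwise `MISMATCH`; residue pairs absent
from the table are treated as partial on all four bases (an uninformative
motif should lower confidence, never manufacture mismatches; a
`mismatch-all` policy is available). Alignment scores weight the classes
1 / 0.5 / 0, the minimal monotone scoring consistent with a three-class
model; no probabilistic weighting is attempted.

Orientation is fixed: motif 1 (N-terminal) pairs with the 5'-most base, one
base per motif, no flanking base. Published binding windows for this family
are sometimes quoted as 17 nt against a 16-motif protein; whether the extra
5' base is contacted is unresolved, so the package scores exactly
`length(array)` bases and treats any 17th position as display context. The
16-nt genomic site coordinates are used for all scanning arithmetic.

```{r code}
tbl <- loadCodeTable()
arr <- rpf2LikeArray()
iupacString(predictRecognition(arr, tbl), "strict")
```

## Searches

All searches enumerate every window (overlaps included — exhaustiveness is
the point of an off-target audit), report 1-based inclusive coordinates on
the forward strand with a strand flag, and are checked in the test suite
against a brute-force window enumerator on random sequences. Genome scans
cover both strands; transcript scans the sense strand only, because PPR
binding is to RNA. C/U discrimination is the weakest point of the code, so
`findNearMatches()` optionally counts C↔U differences as half a mismatch
(`cuLenient`), with thresholds applied to the rounded-up total; the default
keeps C↔U as a full mismatch.

`buildOfftargetPattern()` generalizes a design target using the variation
observed across the parent's natural targets: unanimity keeps the base, a
shared purine/pyrimidine class containing the design base emits R/Y, and
anything else emits N. By construction a pattern built this way never
excludes the natural targets that drove the degeneracy; the audit pattern
used in the shipped reference (`NAAAURCGACCUNUCY`) is carried as a literal
input with its published content.

## Re-design rules

A motif is edited only when its current pair does not already classify the
new target base as perfect; partial positions are upgraded by default
(`keepPartial = TRUE` preserves them), because the aim is a predicted
all-perfect design. When several pairs encode the target base, the pair
sharing more residues with the current pair wins (minimal scaffold
perturbation), with remaining ties broken by a fixed canonical order
(T,N) > (N,D) > (T,D) > (N,N) > (S,N) > (S,D) so the design is
deterministic. `emitProtein()` substitutes only positions 5 and 35 of the
edited motifs; codon-level gene synthesis is out of scope.

## Clone decomposition and its intrinsic ambiguity

A cRT-PCR clone reads across the ligation junction of a circularized RNA:
prefix = molecule 3' part, suffix = molecule 5' part. Anchors are exact
matches of at least `minAnchor` nt (default 12 — long enough that a random
anchor placement in a kilobase transcript is vanishingly unlikely, short
enough to tolerate short products). Junction bases assignable to neither
anchor are returned as the untemplated insert. When a junction base could
extend either anchor, the molecule 5'-end anchor wins, so extra bases stay
attached to the 3' end of the upstream product — where untemplated
adenosines occur biologically.

This resolution cannot beat an intrinsic ambiguity: an untemplated A (or a
genuine product end) adjacent to template sequence that happens to continue
with the same base is unidentifiable in principle. The property tests
therefore assert exactness wherever the junction is unambiguous, and a
consistent, documented shift (both ends move in step) where it is not.
Modal-end inference is robust to this: `inferCleavage()` takes plurality
counts of in-window 5' and 3' ends, breaking count ties toward the larger
gap with a warning. Whether the gap arises from two cuts or one cut plus
3'→5' trimming is an interpretation flag (`model = "trim"` by default, the
trimming scenario being the one supported by untemplated A tailing); it
does not change coordinates. The gap convention is fixed as
`threeStart - fiveEnd - 1` (both product ends exclusive). Because the
reference point of a statement like "cleavage n nt downstream of the site"
is ambiguous, `cleavageDistances()` reports distances from both the site
start and the site end and does not arbitrate.

## Fold-change estimation

The estimator is intentionally minimal: median-of-ratios size factors
(computed over transcripts with nonzero counts everywhere, rescaled to
median 1), then `log2((mean2 + pc)/(mean1 + pc))` with pseudocount 0.5 and
a seeded percentile bootstrap over replicates (1000 resamples by default).
It is a documented stand-in adequate for recovering a planted fold change
on a 33-transcript matrix; dispersion shrinkage, Wald tests and FDR
control are deliberately absent. The size-factor step is cross-checked in
the tests against DESeq2's reference implementation of the same statistic.

## What the simulators emulate — and what they do not

`simulateTranscriptome()` plants exact or k-mismatch site copies in random
transcripts; `simulateClones()` realizes a cleavage event as cRT-PCR clones
of both products plus `GGG`-adapter RACE clones, with seeded end jitter
(30% of ends move by 1–5 nt), 1–3 untemplated adenosines at molecule 3'
ends with probability 0.2, and uniform substitution errors at 1e-4 per
base — the scale of Sanger sequencing of cloned PCR products, which is what
the assay produces; `simulateCounts()` draws negative-binomial counts with
variance mu + alpha*mu^2, alpha = 0.05 (ordinary RNA-seq-like biological
overdispersion), per-sample log-normal library scalars, and planted fold
changes. The default scenario mirrors the study shape: 33 mitochondrial
transcripts, 4 + 4 replicates, one transcript (nad6) at fold change 0.25.

Every generator is a deterministic function of (config, seed). They do not
model RNA secondary structure, positional coverage bias, adapter chimeras,
or read-level (FASTQ) data, so passing tests demonstrate correctness of the
algorithms under clean, known truth — not performance on raw sequencer
output.

With 4 + 4 replicates and alpha = 0.05, the per-replicate coefficient of
variation is at least sqrt(0.05) ≈ 22%, so the sampling sd of the log2
fold-change estimate is ≈ 0.23; a single simulated experiment recovers the
planted −2 to within ±0.3 about 81% of the time, and the estimate is
unbiased to within ≈ 0.07. Recovery claims are therefore phrased on the
mean over seeded replicate simulations wherever a tight tolerance is
needed; the per-run spread is a property of the planted design, not of the
estimator.

## The synthetic reference

The integration-scale fixtures are built by `syntheticMitoGenome()`: a
367,808-bp random background (fixed internal seed; the reference is a fixed
object, not a per-run sample) carrying a stand-in for the Col-0
mitochondrial genome's published landmarks — the nad6 transcript model
(179 nt 5'-UTR + 601 nt CDS, no stop codon or 3'-UTR, mature length 780 nt,
5' end anchored at 164,694 so that CDS +349 falls at 165,221), the design
binding site at 165,221–165,236, the cleavage coordinate 165,269, a cox3
locus whose natural site lies 471–455 nt upstream of its start codon and
differs from the nad6 window at exactly 3 of 17 positions, a minus-strand
nad9 locus (site 301–286 nt upstream), an rps3 locus carrying the
single-C/U-mismatch off-target site, and 29 further random transcripts.
After planting, the background is sanitized so no spurious window matches
the audit pattern with fewer than two mismatches on either strand —
enforcing by construction the uniqueness the real transcriptome search
observed. One base of defined junction context is placed immediately 5' of
the cleavage coordinate so that ligation junctions at the modal product
ends are unambiguous. Everything is generated in code; no genuine genome
sequence is shipped, and the synthetic sequences must not be mistaken for
the real loci — only the coordinates and the match/mismatch structure are
faithful.

```{r reference}
ref <- syntheticMitoGenome()
design <- designRetarget(rpf2LikeArray(), ref$designTarget, loadCodeTable())
designEdits(design)
scanArray(designedArray(design), ref$genome, loadCodeTable(),
          minScore = 16, bothStrands = TRUE)
```

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere except BED output (0-based
  half-open, converted only at the I/O boundary, with the conversion
  round-trip under test).
* T and U are interconverted at entry points; internal state is RNA.
* `N` in a subject sequence matches only an `N` pattern position, scores
  weight 0 in array scans, and counts as a mismatch in literal searches.
* Empty inputs: an empty clone set yields an empty FASTA; an empty end map
  cannot be turned into a cleavage event (error, not a guess); an empty
  stage list in `runPipeline()` writes a manifest only.
* Problem sizes in the shipped tests: brute-force search oracles run on
  ~200 random sequences of 0.2–5 kb; the design round-trip property runs on
  1000 random 10–20-motif targets; clone round-trips use 120–200 clones;
  fold-change recovery uses 20–40 seeded replicates of the 33 × 8 default
  scenario.

## Known limitations

* The PPR code here is the canonical P-class table; PLS-class motifs,
  probabilistic scoring and structure-based binding models are out of
  scope.
* The RPF2-like array ships with synthetic residue content (the real
  protein's motif annotations are not modelled); design tests validate
  properties of the design algebra, not a published protein sequence.
* The endonuclease acting at a distance from the binding site is unknown;
  the package maps and reports cleavage, it does not model the mechanism.
* Fold-change estimation is a stand-in; for real count data a full
  differential-expression framework should be used instead.
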