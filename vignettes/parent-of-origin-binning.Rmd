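---
title: "Parent-of-origin binning of hybrid RNA-seq: models and methods"
author: "hybridbin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parent-of-origin binning of hybrid RNA-seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridbin)
```

## The problem

Interspecies hybrids transcribe both parental haplotypes. Allele-specific
expression (ASE) — an imbalance between the maternal and paternal copy —
is detectable from RNA-seq provided each read pair can be attributed to
the parental haplotype it was transcribed from. A common design aligns
every read pair to the two parental references (transcriptomes or
genomes) and compares the alignments. The difficulty is that short-read
aligners frequently favour the wrong reference: between closely related
genomes many read pairs align equally well, or nearly so, to both, and
systematic map bias then masquerades as ASE.

hybridbin treats the choice between the two alignments as a supervised
binary classification problem. Reads of *known* parental origin (RNA-seq
of the parents themselves) provide labels for free: every parental read
pair aligned to both references is a training example. The trained
classifier is then applied to hybrid reads, where the origin is the
unknown of interest.

## Alignment filtering

The package consumes coordinate SAM/BAM produced by any aligner that
emits the `AS` (alignment score), `NM` (edit distance) and `MD`
(mismatch/deletion positions) optional tags. Before feature extraction,
records are filtered the standard way for this design:

* **proper pairs only** (`FLAG & 0x2`) — both mates aligned in the
  expected orientation and distance;
* **primary alignments only** — secondary (`0x100`) and supplementary
  (`0x800`) records are dropped so each read pair contributes exactly
  one alignment per reference;
* **mapping quality at least 1** — this removes records the aligner
  itself flags as hopeless while *retaining* multireads, which are
  integral here: stricter MAPQ cuts discard precisely the reads whose
  assignment is ambiguous between references, i.e. the interesting
  ones. Aligners that report MAPQ 255 ("unavailable") pass the numeric
  threshold and are accepted.

Records missing `AS` or `NM` cannot feed the feature extractor; they are
counted and skipped, and the skip counts are reported. Records missing
only `MD` are retained: mismatch counts then fall back to
`max(0, NM − INS − DEL)`, with positional (quality-aware) mismatch
information unavailable and logged as such.

## The 53-feature representation

Each read pair aligned to both parents is summarised by 53 features,
laid out in a frozen, versioned column order (`feature_names()`):

1. **40 per-read-alignment features** — for each of the four alignments
   (R1 and R2 against parent 1 and parent 2), ten aligner-facing
   counts: alignment score (AS), edit distance (ED, the `NM` tag
   verbatim), mismatches (MM), high-quality mismatches (HQMM), gap
   opens (GO, distinct indel runs), gap extends (GE, total indel
   bases), inserted bases (INS, HQINS), deleted bases (DEL, HQDEL).
2. **11 difference features** — for AS, ED, MM, HQMM, GO, GE, INS, DEL,
   HQINS, HQDEL and MAT (matched bases), the sum over the pair's two
   alignments to parent 2 minus the equivalent sum for parent 1.
3. **Span difference** — the length of the pair's projection onto the
   parent-2 reference minus the same for parent 1. The projection
   length is computed from coordinates (rightmost alignment end minus
   leftmost start, inclusive — identical to |TLEN| for proper pairs),
   so the definition extends to spliced genome alignments where TLEN
   conventions differ between aligners.
4. **PARENT** — +1 if parent 2 has the greater summed alignment score,
   −1 if parent 1 does, 0 if tied.

Raw matched-base counts, raw spans and read lengths are deliberately
**not** features, only their parent-to-parent differences: their
absolute values are properties of the sequencing library (read length,
insert size), and a model keying on them would not generalize across
runs.

### High-quality events

An event is *high-quality* (HQ) when the base calls involved carry the
maximal quality character of the encoding (e.g. `F` for modern
Illumina): the one read base of a mismatch or insertion, and **both**
read bases flanking a deletion. A deletion at the alignment edge has
only one flanking base and is never HQ. The maximal character is a
parameter (`detect_max_quality_char()` offers auto-detection from a
sample of records; a manual override always wins). The HQ distinction is
what lets the model separate true inter-parental sequence differences
(which occur at ordinary, mostly maximal-quality positions) from
sequencing errors (which concentrate at low-quality positions).

### The soft-clip rule

Soft-clipped bases are treated as aligned-and-mismatched: each `S` base
increments MM (and HQMM when its quality is maximal) and the aligned
length, and never counts as matched. A `1S99M` record is therefore
scored as 100 aligned bases with one mismatch, and the extractor's MM
can exceed the aligner's `NM` tag, which excludes clipped bases. The
rationale: a clipped base is a read base the aligner could not
reconcile with this reference, which is exactly the evidence the
classifier needs; silently ignoring clips would make a heavily clipped
alignment look clean. ED is nevertheless copied verbatim from `NM`, so
both views of the alignment are available to the model. Hard clips
carry no bases and are ignored. `=`/`X` operations are folded into `M`
semantics; `N` (skipped intron) operations consume reference span but
generate no events, so spliced genome alignments are handled uniformly.

## The three deciders

* **Aligner choice** (baseline A): run the aligner once on the
  concatenation of the two references and read the parent off the
  primary alignment. By construction this decider sees only the
  reference identity; ties are impossible (the aligner always reports
  something), but its internal tie-breaking is opaque and is where
  reference-order bias enters.
* **Score comparison** (baseline B): align to the two references
  separately and pick the side with the greater `AS(R1) + AS(R2)`.
  Exact ties are broken uniformly at random — reported separately, but
  broken so that accuracy statistics remain comparable across
  deciders. This decider sees only the four AS values.
* **Random forest post-processor**: a probability forest over all 53
  features, trained on reads of known origin. Defaults are the standard
  library configuration — 100 trees, Gini impurity, √p candidate
  features per split, fully grown trees — which is deliberately boring:
  experimenting with more trees or alternative architectures has not
  been found to help this task, and a fixed default keeps runs
  comparable. Feature importances use mean decrease in impurity,
  normalized to sum to one. The predicted parent is P2 when the P2
  probability exceeds 0.5; an exact 0.5 is broken by a seeded coin and
  recorded. The fitted model stores its feature schema, configuration
  and seed, and refuses to predict on tables with a different schema.

Class weighting (for bias mitigation) is exposed in `model_config()` but
off by default.

## Dataset construction

`join_by_read()` pairs the two filtered alignment streams by read id
(mates resolved from FLAG bits, never file adjacency). Pairs aligning
to exactly one reference are reported separately and never enter the
model: exclusive mapping is dominated by reference completeness
artifacts and is a poor origin signal. `mix_hybrid()` combines labeled
parental pairs 50:50 (configurable), balanced to the available supply
and interleaved so that even and odd positions come from different
parents — any prefix of the stream is then class-balanced, which
discourages the model from learning a class prior. The 50:50 mixture is
a model of hybrid RNA-seq with no ASE; it deliberately overlooks
isoform-abundance differences between alleles.

`split_train_test()` is positional: the first 80% of the stream trains,
the rest tests. Input order is FASTQ order, which is essentially random
with respect to genomic position, and a positional split keeps the
protocol reproducible without a second source of randomness. The
`holdout_refs` option moves every pair touching a named reference
sequence (on either parent's side — conservative against leakage) to
the test set, for checking that a model generalizes to parts of the
reference it has never seen rather than memorizing transcript-specific
quirks.

## Evaluation panel

With P2 the positive class by convention (configurable), the panel
reports accuracy, sensitivity, specificity, precision, F1 and positive
preference as percentages, and MCC on its natural [−1, 1] scale:

* accuracy = 100·(TP + TN)/(TP + FP + TN + FN)
* sensitivity = 100·TP/(TP + FN), specificity = 100·TN/(TN + FP)
* precision = 100·TP/(TP + FP), F1 = 200·TP/(2TP + FP + FN)
* MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN))
* Pos Pref = 100·(TP + FP)/(TP + FP + TN + FN)

A zero factor in the MCC denominator yields MCC 0 (the standard
convention; flagged via an attribute). AUROC uses the
probability-ranking (Mann–Whitney) definition with midrank handling of
score ties; AUPRC is the step-function area with tied scores entering a
threshold together. Both are reported as percentages to match the
layout of conventional results tables; deciders without scores leave
them blank. Pos Pref reads 50% for unbiased predictions on a balanced
set; its deviation from 50% is the map/class bias.

For case studies on real hybrids, where truth is unknown,
`bias_baseline_compare()` makes the bias-baseline logic explicit: the
decider's positive preference measured on reads of *known* parental
origin — not 50% — is the no-ASE expectation for the hybrid, and the
observed hybrid preference is compared against it with an exact
binomial interval. A hybrid preference whose interval contains the
parental baseline is consistent with no transcriptome-wide ASE.

## The simulator

Real benchmark data for this problem is multi-gigabyte public RNA-seq;
the bundled simulator instead makes every pipeline stage testable
against exact ground truth, at desk scale, with no downloads.

**References.** An ancestral transcript sequence is mutated per site
into the two parents: substitutions at `divergence_snp_rate` (derived
allele assigned to a random parent) and indel events at
`divergence_indel_rate` with geometric lengths. The construction keeps
the explicit column-wise pairwise alignment of the two parents, so both
sequences, their coordinate maps, the variant table and the exact
homologous alignment of any window are all derivable — nothing is ever
realigned by search, and ground truth is exact rather than estimated.
This idealizes alignments slightly (a real aligner may place an indel
differently within a homopolymer, for instance), which is the right
trade-off for validating an extractor against a ledger.

**Reads.** Fragments are drawn uniformly from transcripts with normal
insert lengths (truncated at twice the read length, so mates never
overlap and per-pair event arithmetic stays simple), 2×100 by default.
Base qualities are two-level — the maximal character or one lower
character — so that HQ classification is binary-testable; realistic
quality profiles are out of scope. Sequencing errors are substitutions
at `seq_error_rate`; an error base keeps the maximal quality character
with probability `error_hq_prob` (default 0.05, i.e. qualities are
informative but not perfect). This coupling is the simulator's model of
the real correlation between base quality and error probability, and it
is what gives the HQ features their discriminative value.

**Ground-truth SAM.** Each read is written against both references with
proper-pair flags, MAPQ 42 and exact POS/CIGAR/TLEN/`AS`/`NM`/`MD`. The
alignment against the non-true parent follows the reference column
alignment through the read's window. Alignment scores use end-to-end
short-read scoring: 0 − 6·MM − 5·GO − 3·GE, the conventional penalties
of end-to-end Bowtie2-style alignment, so AS magnitudes are realistic.
Ledger event counts are computed column-by-column from the planted
variants and errors — a code path independent of the CIGAR/MD text —
so the extractor-versus-ledger round trip is a genuine two-route check.

**The planted tie mechanism.** In real congeneric data a sizable
fraction of read pairs receives *equal* alignment scores against the
two references (conserved regions, gene families), and this is exactly
where score comparison degenerates to a coin flip. The `congeneric`
preset plants such ties at a declared rate: for a `tie_rate` fraction
of pairs, sequencing errors are placed at covered variant sites so that
the per-parent mismatch counts come out exactly equal (with k covered
substitution sites, c errors converted to the other parent's allele and
h to a third base, the tie condition is 2c + h = k). The alignment
scores then tie exactly — score comparison must flip a coin — while the
surviving variant sites still show high-quality mismatches against the
wrong parent only, so quality-aware features remain informative. This
is the designed analogue of "equally good alignments that are not
equally plausible", the regime where a post-processor adds the most
value. Pairs covering indel variants are excluded from planting to keep
the arithmetic exact; the planted fraction is the expected observed tie
rate.

**Presets.** `scenario_suite()` fixes three regimes: `zero_divergence`
(identical parents; the null control — every comparison feature is
zero, the PARENT feature identically so, and no decider can beat 50%),
`low_divergence` (0.05% substitutions; most pairs cover no variant and
score comparison sits barely above chance, the within-species regime
where the method is *not* recommended), and `congeneric` (5%
substitutions, 0.2% indels, 0.5% sequencing error, 15% planted ties —
the between-congener regime the method is designed for).

**What the simulator does not emulate** — and hence what passing tests
do and do not show about real data: multi-mapping and paralogy (beyond
the planted-tie abstraction), aligner-specific failure modes and
clipping behaviour, spliced alignment (the extractor handles `N`
operations from real data, but the simulator is transcript-level),
isoform-abundance differences between alleles, realistic quality
profiles, and indel sequencing errors. Results on the simulator
validate the machinery — extraction exactness, the deciders'
contracts, the statistical behaviour across divergence regimes — not
field performance on any particular organism pair.

## Numerical and design choices

* MCC with a zero denominator factor is 0; flagged, never NaN.
* Model probability exactly 0.5 → seeded coin, recorded; score-ties →
  seeded uniform draw, reported as a tie fraction.
* Concatenated-reference ties in the simulator fall deterministically
  to parent 1, emulating the reference-order bias of real aligners;
  this is why the aligner-choice baseline shows a depressed positive
  preference on tie-rich data while score comparison (random ties)
  does not.
* Edge deletions are never HQ (one flanking base does not satisfy a
  two-base requirement).
* The pair span is inclusive (rightmost end − leftmost start + 1),
  matching |TLEN| for proper pairs; only the difference enters the
  feature vector, so the convention cannot affect the model.
* "First N" pairs are counted on the joined stream in parent-1-file
  order, making runs reproducible from the inputs alone.
* All randomness (simulation, tie-breaking, forest training) flows
  from explicit integer seeds; identical seeds and inputs give
  byte-identical feature tables and predictions.

## Problem sizes used in validation

The shipped test suite validates the extractor round trip on 10,000
simulated reads per preset, the metrics panel against brute-force
oracles on 1,000 random confusion tables, the null control and the
tie-rich benchmark on 10,000 mixed pairs each, and divergence
monotonicity (0 → 0.002 → 0.01 → 0.05 substitutions/site) on 20,000
pairs per point. These sizes give binomial standard errors of about a
percentage point on held-out accuracies — small enough to separate the
regimes of interest while keeping a full validation run on a laptop in
minutes.

## Limitations

The package post-processes alignments; it does not align, trim, or
quantify. Gene-level ASE statistics downstream of binning (replicates,
shrinkage, multiple testing) are intentionally out of scope — the
output is a per-read-pair assignment plus the bias baseline needed to
interpret aggregate preferences. Between very similar genotypes
(within-species crosses), no decider — including the model — finds
enough signal, and the honest recommendation is not to use this design
there. Performance on real hybrids depends on phenomena the simulator
does not model (see above); the case-study tooling exists precisely
because real-hybrid accuracy cannot be measured directly.
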