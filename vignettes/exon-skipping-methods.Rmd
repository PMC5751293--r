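---
title: "Detecting exon skipping with rotation forests: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting exon skipping with rotation forests: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotaskip)
```

## The problem

A cassette (alternative) exon is spliced into some of its gene's mature
transcripts and skipped in others; a constitutive exon is always
included. Deciding which of the two a candidate exon is, from bulk
RNA-Seq of two tissues plus the genome sequence around the exon, is a
binary classification problem: **ES** (exon skipping) versus **non-ES**.
Evidence of skipping comes from spliced reads that join the two flanking
exons directly (exclusion-junction reads), evidence of inclusion from
reads inside the exon body and from reads spanning either flank-to-exon
junction. Because inclusion levels differ between tissues for genuinely
alternative exons, a two-tissue contrast carries much of the signal.

`rotaskip` implements the whole chain — read counting, feature
construction, classification, evaluation — plus a read simulator so the
pipeline can be exercised and validated without any external data.

## Read counting

Reads are simplified to blocks of aligned reference intervals (0-based,
half-open; splices are the gaps between blocks). Per event and tissue,
six counters are computed by `count_set()`:

* `n_exon`, `n_up_intron`, `n_down_intron`, `n_gene` use
  **intersection-strict** counting: a read counts for a region only if
  every aligned base of every block lies inside it. This matches the
  strictest standard of common htseq-style counters and makes the count
  of tiled reads equal the region's *effective length*
  $L - L_r + 1$ for read length $L_r$.
* `n_ni` (inclusion support) is the union of exon-body reads and
  anchored junction reads on either inclusion junction. A junction read
  must have a block ending exactly at the donor coordinate and the next
  block starting exactly at the acceptor, with at least $o$ aligned
  bases on both sides (the *anchor*). The number of distinct junction
  placements is $L_r + 1 - 2o$.
* `n_ne` (skipping support) counts anchored reads on the
  flank-to-flank exclusion junction.

The inclusion counter includes exon-body reads because the inclusion
isoform's effective length is
$L_e - L_r + 1 + 2(L_r + 1 - 2o)$ — exon placements plus the two
junctions — and counter and denominator must describe the same set of
placements for the normalised value to be interpretable. A single read
counts at most once per counter, and no read can support both `n_ni`'s
junction component and `n_ne` (the splice coordinates are incompatible).

Junction matching is exact-coordinate by design: tolerating near-miss
splice sites would trade determinism for a heuristic that belongs in the
upstream aligner. The anchor defaults to $o = 8$ bp, a common
junction-evidence threshold for short-read data; it is configurable
everywhere it appears.

## Features

48 features per event, in a fixed, documented column order
(`rs_feature_names()`), grouped as:

* **Initial (12)** — the six raw counts per tissue (muscle `s_*`, then
  brain `b_*`).
* **Equilibrium (21)** — per tissue the six counts normalised to reads
  per effective position per mapped read, scaled by $10^9$:
  $\mathrm{NORM}_x = N_x \cdot 10^9 / (\mathrm{eff}_x \cdot T)$ with
  $T$ the tissue's total mapped reads; the percent-spliced-in
  $P = \mathrm{NORM}_{ni} / (\mathrm{NORM}_{ni} + \mathrm{NORM}_{ne})$
  per tissue; and seven divergences (brain minus muscle) of the
  normalised counts and of $P$. The $10^9$ scaling is kept verbatim
  rather than converted to the RPKM per-kilobase-per-million
  convention, so normalised values are directly comparable across the
  six counters, which have very different effective lengths.
* **Sequence (15)** — the three region lengths (upstream intron, exon,
  downstream intron) and the A/C/G/T counts of each region.

Selectors for the five experimental subsets (`initial`, `equilibrium`,
`rnaseq` = 33, `sequence`, `rs` = 48) are provided by
`feature_set_columns()`.

Choices worth stating explicitly:

* **$P(0,0) := 0$.** An event with no junction evidence in either
  direction has an undefined inclusion fraction; defining it as 0
  avoids NaN propagation into the model. `rs_features()` additionally
  returns a `no_junction_evidence` flag (not part of the 48 columns) so
  callers can treat such events specially.
* **Nucleotide counts are raw, not length-normalised.** Lengths are
  separate features, so the classifier can learn any normalisation it
  needs; keeping counts integral also makes them exactly testable.
  Ambiguity codes (N and friends) count toward nothing.
* **Strand handling.** Lengths are strand-invariant. Composition is
  read in transcriptional orientation: for minus-strand events each
  region's slice is reverse-complemented (equivalently, A/T and C/G
  swap). Region *slots* keep their genomic identity — the
  upstream-intron slot is always the genomically upstream intron — so
  that the plus/minus relationship stays a pure base-complement swap,
  which is the property the tests pin down. A `genomic_orientation`
  flag disables complementing for replication of strand-agnostic
  analyses.
* **Fixed feature order.** The order (initial, equilibrium, sequence;
  within blocks, table order muscle/brain/divergence) is persisted in
  feature-table headers, making stored models column-order-safe.

## The classifier

`rotation_forest()` implements the rotation-forest ensemble from
scratch. Per tree:

1. the $D$ features are randomly partitioned into subsets of size $M$
   (default $M = 3$, the value the method's originators recommend; a
   smaller remainder subset is allowed when $M \nmid D$);
2. each subset is centred and rotated onto the principal axes of its
   covariance (all axes are kept — axes with near-zero eigenvalue are
   still orthonormal — so each block, and hence the assembled $D \times
   D$ matrix $R^*$, is orthogonal; a fully constant subset falls back
   to an identity block with a warning);
3. an unpruned CART (Gini) is grown on the rotated data $X R^*$.

Prediction rotates each instance per tree, averages the trees' leaf
class distributions, and takes the class of maximum mean confidence;
an exact tie goes to the positive (ES) class, because sensitivity to
true skipping events is the operating priority of this kind of screen.
The default ensemble size is $L = 10$ trees.

The per-subset PCA is computed on all training rows by default. The
classic variant — dropping a random subset of classes and taking a 75%
bootstrap before each subset's PCA — is available behind
`class_sample_fraction` and `bootstrap`, off by default, since the
plain reading of the procedure rotates the full sample.

The CART base learner is part of the package rather than a wrapped
dependency: that keeps split tie-breaking fully specified (lowest
feature index, then lowest threshold; thresholds are midpoints of
adjacent distinct values), lets models serialise losslessly to
versioned JSON (`write_rotation_forest()` /
`read_rotation_forest()`), and makes fits bit-reproducible from the
seed. The test suite cross-checks it against an independent CART
implementation (`rpart`) on a task whose optimal tree is unique.
Eigenvector signs are normalised (largest-magnitude loading positive)
so rotations are platform-independent.

Numerical tolerances: rotation orthogonality is asserted to $10^{-8}$;
PCA eigenvalues are not thresholded (retaining an orthonormal axis of
zero eigenvalue is harmless and keeps $R^*$ square); split gain must
exceed $10^{-12}$ for a node to split, which is how pure or constant
nodes terminate.

## Evaluation

`confusion()` tallies TP/TN/FP/FN against a declared positive class;
`accuracy()`, `specificity()` and `sensitivity()` return percentages at
full precision, with `report_percent()` applying the conventional
one-decimal half-up rounding at the reporting layer only. A metric with
a zero denominator is `NA` (undefined), never silently 0.
`roc_curve()` sweeps thresholds over the score order, collapsing tied
scores into single steps, and `auc()` integrates by trapezoid — exactly
the Mann–Whitney concordance probability, with ties at half credit.
Both are property-tested against a brute-force pair-concordance oracle
and cross-checked against an independent ROC implementation.

## Labelling and splits

Consensus labelling over three detector hit-lists
(`consensus_label()`): at least two hits → ES, zero hits → non-ES,
exactly one hit → unlabeled. Unlabeled events are kept in tables but
excluded from training and testing — discarding them entirely would
hide how many borderline calls the consensus made.
`stratified_split()` draws exact per-class test counts (the canonical
shape used throughout is 51 ES + 255 non-ES held out, leaving 102 +
510 for training), seeded; `holdout_remainder()` sizes an independent
evaluation set from a catalogue total.

## The simulator and what it does (not) show

`simulate_es_study()` generates each event on its own chromosome with
layout pad / flanking exon / intron / cassette exon / intron / flanking
exon / pad, i.i.d. base composition (default 30/20/20/30), and
uniform-random region lengths (exon 100–250 bp, introns 150–600 bp,
flanks 150 bp, 100 bp padding). Reads are single-end, 32 bp, error-free;
per placement class the read count is Poisson with mean
$\psi \cdot d \cdot (\text{number of placements})$ at sequencing depth
$d$ (default 2 expected reads per placement), with inclusion evidence
weighted by the inclusion level $\psi$ and exclusion evidence by
$1 - \psi$, plus a 2% intronic background so the intron counters are
non-trivially exercised. The defaults encode a strongly
tissue-differential design: skipped exons at $\psi_B = 0.3$,
$\psi_S = 0.9$; constitutive exons fully included in both tissues.
After normalisation the effective lengths cancel, so the expected
measured $P$ equals $\psi$ (`expected_p()` derives this algebraically
and doubles as the end-to-end oracle).

What passing on this simulator shows: the counting, normalisation,
feature assembly, training and evaluation chain is internally
consistent, recovers the inclusion level it was fed, and separates
well-separated classes at the canonical 612-train / 306-test shape with
sensitivity and specificity above 95%. What it does not show: behaviour
under alignment error, sequencing error, paired ends, overlapping
isoform structure beyond one cassette exon, GC or positional bias, or
biologically realistic sequence composition — real-data performance
cannot be inferred from these tests. The simulated problem sizes
(hundreds of events, $10^5$–$10^6$ reads) were chosen as the smallest
at which the full design shape is exercised meaningfully.

## Known limitations

* Two tissues only, by construction of the divergence features.
* One cassette exon per event; mutually exclusive exons, retained
  introns and alternative splice sites are out of scope.
* Junction matching is exact-coordinate; slop tolerance must be
  handled by the aligner.
* Multi-mapped reads are counted once per supplied record;
  deduplication is the input adapter's responsibility.
* The independent-detector stage that produces hit-lists for consensus
  labelling (and the alignment stage producing reads) is consumed, not
  reimplemented.
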