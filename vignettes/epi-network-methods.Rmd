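---
title: "Enhancer-promoter interaction networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enhancer-promoter interaction networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epinets)
```

## The problem

Enhancers regulate transcription from a distance, and which enhancer
drives which gene differs between cell types. This package implements a
desk-scale version of an enhancer-promoter interaction (EPI) analysis
across six neuronal cell types spanning two differentiation stages:
three progenitor types (ESC, NSC, NPC) and three mature neuron types (AD
inhibitory, Ngn2 excitatory, Motor). It covers simplified
Activity-by-Contact (ABC) scoring, the activity filters that define an
EPI, collapsed and subset network construction, sub-structure
classification, cross-cell-type element comparison, transcription-factor
presence clustering, and resampling tests for disease-variant
enrichment. A synthetic-data generator with a ground-truth manifest
makes every inference step testable by parameter recovery.

## The ABC score

For a candidate enhancer $e$ and a promoter with TSS $p$, the score is

$$\mathrm{ABC}(e, p) \;=\; \frac{A_e \, C_{ep}}{\sum_{e' \in W(p)} A_{e'} \, C_{e'p}},$$

where $A_e$ is enhancer activity, $C_{ep}$ the estimated contact
frequency, and $W(p)$ the set of candidate enhancers whose midpoint lies
within 5 Mb of the TSS. Enhancers outside the window enter neither
numerator nor denominator, so scores over $W(p)$ sum to 1 exactly.

Choices behind each term:

* **Activity** is the geometric mean of the ATAC-seq and H3K27ac peak
  read counts, `sqrt(atac * h3k27ac)`, the combination used by the ABC
  model this score simplifies. Arithmetic mean and raw product are
  available (`enhancer_activity(method=)`); because of the per-promoter
  normalisation only ratios between enhancers matter, so the choice
  shifts scores only when the two assays disagree strongly. Units
  cancel, so any non-negative per-peak quantity (raw counts, RPKM-like
  values) is acceptable input.
* **Contact** is a power law with a floor,
  $C(d) = s\,\max(d, d_{\min})^{-\gamma}$, with defaults $\gamma = 1.0$
  and $d_{\min} = 5000$ bp. The exponent near 1 matches genome-wide
  contact decay estimates at these scales; the floor keeps contact
  finite at zero distance and flat below the resolution where a power
  law stops being meaningful. The prefactor $s$ cancels in the score
  (bit-exactly for power-of-two factors, to rounding error otherwise) -
  the package tests this invariance.
* **Distance** is measured enhancer midpoint to TSS. Candidate enhancers
  are 500 bp wide (peaks normalised to 500 bp around their apex), so
  midpoint-vs-edge differences are negligible against $d_{\min}$.
* **Degenerate promoters**: if every in-window activity is zero, all
  scores are defined as 0 with a warning rather than 0/0.

An interaction is called active when its ABC score is at least 0.02
**and** its target gene is expressed above 1 TPM (strictly) in that cell
type. The 0.02 boundary is kept inclusive: the operational rule is that
interactions *below* 0.02 are removed. The TPM rule is strict
("greater than 1"), so a target at exactly 1 TPM is dropped.

## Networks

* **Collapsed network**: the six filtered per-cell-type tables
  concatenated with duplicates kept - the same enhancer-gene pair active
  in three cell types contributes three records. A separately maintained
  enhancer list merges any intervals overlapping by at least 1 bp
  (half-open coordinates; book-ended intervals do not overlap). This
  pooled list is the resampling universe for the empirical test.
* **Subset network**: enhancer regions of the concatenated EPIs are
  merged whenever they lie within 100 bp of each other (transitively);
  each merged EPI collects one ABC score per cell type, aggregated over
  its members by the maximum (the default preserves "non-zero in cell
  type X"; mean aggregation is available). Categories are then assigned
  in a fixed decision order: non-zero in >= 5 of 6 cell types is
  ubiquitous (Ubi); exactly one non-zero is that cell type's own
  category; >= 2 non-zero all progenitor is Progenitor; all mature is
  Mature; anything else (2-4 cell types mixing stages) is Removed. Ubi
  must be checked before the mixed-stage removal rule because five of
  six cell types necessarily span both stages; with any other order the
  Ubi class would be empty.
* **Sub-structures**: within one cell-type network, each EPI is labelled
  by the 2x2 of enhancer degree (distinct target genes of its enhancer)
  and promoter degree (distinct enhancers of its gene): C1 one-to-one,
  C2 one enhancer to many genes, C3 many enhancers to one gene, C4
  many-to-many. Promoter identity is the gene symbol, not the TSS
  coordinate, so transcript-level TSS variation cannot split a promoter.
  Labels partition each network by construction; the tests verify the
  labels against a brute-force degree count.

## Element comparison

Uniqueness uses the >= 1 bp overlap rule against the original,
pre-merge per-cell-type intervals; promoters compare by exact,
full-string gene symbol (SOX21 never matches SOX2). The interval Jaccard
index merges both sets into union intervals $U$ and computes
$J = i/(a + b - i)$ with $a, b$ the union intervals containing an
element of each set and $i$ those containing both. This is symmetric
even when the two sets resolve the same region into different numbers of
elements, which raw pair counting is not. A base-pair-level alternative
(shared bp / union bp) is available; the element level is the default.

## TF presence and clustering

FIMO-style binding tables are filtered to p strictly below 1e-5 and
multiple motifs of one TF within one enhancer collapse to a single
(tf, enhancer) row. The count matrix holds, per TF and cell type, the
number of distinct network enhancers bound; the weighted matrix divides
each row by the TF's total so rows sum to 1. Row normalisation follows
the stated construction of the weighted matrix; TFs bound nowhere are
excluded rather than producing 0/0 rows. k-means (Euclidean, k = 3, 10
restarts under a fixed seed, best inertia) clusters the weight rows;
clusters are labelled by the difference between their centre's mean
progenitor and mean mature weight - largest difference
`higher_progenitor`, smallest `higher_mature`, middle `equal`, ties
broken by cluster index. Peak-expression grouping assigns each TF the
argmax cell type of its TPM, with exact ties going to the first cell
type in the fixed order (flagged).

## Variant enrichment

Promoter regions span the 2000 bp upstream of the TSS: `[start-2000,
start)` on the + strand, `[end, end+2000)` on the -. Regions are clipped
at chromosome bounds with a warning. An element counts as variant-bearing
if at least one variant overlaps it, however many do.

The **empirical resampling test** asks whether one cell type's elements
overlap variants (or intersect a disease gene list, by exact symbol
match) more than expected: for $r = 1..R$ (default 1000) it draws the
same number of elements uniformly *without replacement* from the
deduplicated pooled collapsed-network elements and recomputes the
statistic. The reported p-value is the standard upper-tail estimator

$$p = \frac{1 + \#\{r : \mathrm{count}_r \ge \mathrm{observed}\}}{R + 1},$$

which cannot reach 0 and is uniformly distributed under the null. The
uncorrected estimator $\#\{\ge\}/R$ is available as `legacy_p = TRUE`
for comparison with pipelines that used it. Significance uses
$0.05/6 = 0.008333$ (rounded to six decimals) for the six per-cell-type
family, and 0.05 for nominal significance. Sampling without replacement
from the deduplicated pool matches "select the same number of regions";
with-replacement sampling would inflate the null variance for large
targets.

**Fisher contrasts** use the exact conditional test (`stats::fisher.test`)
with the conditional-MLE odds ratio; the sample cross-product ratio is
available as an option. The test suite verifies the p-value against an
exhaustive enumeration of all tables with the observed margins, exactly,
for every table total up to 40. For the case/control sub-structure
contrast, the 2x2 rows are (case, control) and the columns are (variant
in an element of the tested category, variant in an element of any other
category); variants hitting no labelled element are excluded, and a
variant hitting elements of several categories counts once in each
column it belongs to - category tests are run independently, one table
per category. The differential-expression contingency filters genes to
FDR strictly below 0.05 and splits them at LFC strictly above 1 (up) or
strictly below -1 (down).

## The synthetic study design

The generator's defaults are the study conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| cell types | 3 progenitor + 3 mature | the six-network, two-stage design |
| enhancers per cell type | 5000 | desk-scale; the sharing-recovery analyses use this size |
| enhancer width | 500 bp | peaks normalised to 500 bp around the apex |
| cell-type-specific fraction | 0.35 | the reported average uniqueness of enhancers |
| stage-shared fraction | 0.40 | produces within-stage Jaccard blocks clearly above cross-stage overlap |
| gene universe | 6000 | leaves a substantial minority of genes untargeted, as in genome-scale annotations, so gene-list backgrounds are meaningful |
| ABC scores below 0.02 | 20% | exercises the score filter boundary |
| TPM values at or below 1 | 20% | exercises the expression filter boundary |
| TFs | 60, bias 0.6 | three archetypes (progenitor / mature / uniform) in equal thirds |
| variants | 125,000 case + 125,000 control | the scale of the de novo variant space the enrichment analyses consume (~250k, evenly split) |
| genome | 2 chromosomes x 30 Mb | large enough that elements occupy a few percent of it |

Generation is by assignment, not post-hoc labelling: enhancers are
placed on a non-overlapping 2-kb grid and each is constructed as
specific (one network), stage-shared (all three networks of one stage)
or ubiquitous (all six), so manifest class fractions match the data
exactly and uniqueness recovery is a genuine end-to-end check of the
overlap machinery rather than a sampling estimate. Shared enhancers are
written at identical coordinates by default; an optional jitter of up to
100 bp shifts each cell type's copy so that both the >= 1 bp overlap
rule and the 100-bp subset merge are exercised. ABC scores are drawn
directly rather than through the scoring module so the network analyses
are testable independently; `generate_activity_peaks()` provides
peak-level input for the end-to-end scoring path. Variants are
single-base, as de novo SNVs dominate the variant sets this emulates.

Planted variant enrichment multiplies the sampling density inside the
target sub-structure's merged elements by the configured factor $m$: a
case variant lands inside the target footprint $T$ with probability
$mT/(mT + G - T)$ for genome size $G$, uniformly within it, and
uniformly outside it otherwise. With $m = 1$ this reduces exactly to a
uniform draw, which is also the control model, so case and control are
exchangeable under the null.

What the generator does **not** emulate: sequence (no FASTA or motifs -
TFBS tables are drawn at the table level), read-level noise, Hi-C
matrices, linkage structure among variants, chromatin-state correlation
between neighbouring elements, and the long-tailed degree distributions
of real networks. Passing recovery tests therefore demonstrates that the
inference machinery is correct under its stated assumptions, not that
those assumptions hold in any real dataset.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open (BED convention) everywhere
  internally; GenomicRanges conversion happens at the module boundary.
* Enhancer identity is the exact (chrom, start, end) triple within a
  cell type - needed to join TFBS tables unambiguously.
* The per-promoter score normalisation is tested to 1e-9; weighted TF
  rows to 1e-9.
* Readers reject rather than coerce: inverted intervals, non-integer
  coordinates, non-numeric TPMs, and duplicate TPM gene symbols are
  errors with the offending line or column named; duplicate EPI rows
  are flagged with a warning.
* Empty networks, all-zero score vectors, all-zero contingency tables
  and k > number of TFs are errors, not silent results.

## Problem sizes used by the checks

The recovery analyses run at deliberately chosen sizes: sharing-structure
recovery at 5000 enhancers per cell type; variant-enrichment power at
1000 enhancers per cell type with 5000 + 5000 variants over 100
replicates, and null calibration at the default ~250k variant space over
1000 replicate draws against one fixed network (the Fisher test needs
realistic in-element counts to attain its nominal level - at a few
hundred variants per arm its discreteness makes it conservative); TF
archetype recovery at 600 enhancers per cell type over 20 seeds; the
empirical-vs-exact comparison on pools of up to 12 elements at 10,000
draws, restricted to configurations whose exact tail lies outside
(0.05, 0.95), where a 10,000-draw estimate resolves the +-0.01
comparison reliably; Fisher-vs-enumeration on every table with total up
to 40.

## Known limitations

* The subset network carries merged enhancer intervals and per-cell-type
  scores but not gene identities; sub-structure labelling operates on
  the per-cell-type networks (the per-EPI labelling; a per-enhancer
  variant is not implemented).
* Interval semantics of the Jaccard index are a package definition
  (union-merged elements); published heatmaps built on other conventions
  will differ in level, though not in ordering, from ours.
* The empirical test treats elements as exchangeable; it does not
  length-match or GC-match draws.
* Real ABC pipelines use Hi-C-derived contact and candidate-region
  calling; the power-law contact here is a stated simplification, and
  headline counts from real datasets are out of scope.
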