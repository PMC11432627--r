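# epinets

Enhancer–promoter interaction (EPI) networks from Activity-by-Contact
scores, for regulatory genomicists studying how enhancer usage changes
across cell types — here, six neuronal cell types spanning two
differentiation stages: progenitors (ESC, NSC, NPC) and mature neurons
(AD inhibitory, Ngn2 excitatory, Motor).

## What it computes

**ABC scoring.** For enhancer *e* and promoter *p*,

    ABC(e,p) = A_e C_ep / Σ_{e' ∈ W(p)} A_e' C_e'p

with activity *A* the geometric mean of ATAC-seq and H3K27ac peak read
counts, contact *C(d) = max(d, d_min)^(−γ)* a power law of genomic
distance (γ = 1, d_min = 5 kb by default), and *W(p)* the enhancers
within 5 Mb of the TSS. An EPI is active when ABC ≥ 0.02 and its target
gene exceeds 1 TPM in that cell type.

**Networks.** The six filtered cell-type tables concatenate into a
*collapsed network* (duplicates kept; overlapping enhancers merged
separately by the ≥ 1 bp rule), and into a *subset network* (enhancers
merged within 100 bp, then categorised by which cell types show a
non-zero score: cell-type-specific, Progenitor, Mature, ubiquitous, or
removed mixed-stage). Each EPI is classified by the 2×2 of enhancer and
promoter degree: C1 one-to-one, C2 one enhancer → many promoters, C3
many enhancers → one promoter, C4 many-to-many.

**Comparisons and inference.** Cross-cell-type uniqueness fractions and
Jaccard matrices for enhancers and promoters; binary and weighted TF
presence matrices from FIMO-style binding tables (p < 1e-5, motifs
collapsed per TF) with k = 3 stage-preference clustering; strand-aware
promoter regions (2 kb upstream of the TSS); an empirical resampling
test — observed variant overlap versus 1000 size-matched draws from the
pooled network, p = (1 + #{draws ≥ observed})/(R + 1), corrected
threshold 0.05/6 = 0.008333 — and exact Fisher contrasts (case vs
control variants by sub-structure; differential expression by network
membership).

**Synthetic study generator.** `sim_config()` + `generate_*()` build the
whole input space with known ground truth: sharing classes assigned by
construction (35% cell-type-specific, 40% stage-shared by default),
scores and TPMs straddling their filters, TF binding with planted stage
bias, and case/control variants with an optional enrichment planted into
a chosen sub-structure. Every downstream module is validated by
recovering what was planted.

## Worked example

The `analysis/` scripts run the full study in order and write tables
under `results/`:

```sh
Rscript analysis/01_simulate.R          # synthetic six-cell-type study
Rscript analysis/02_score_and_filter.R  # ABC scoring + activity filters
Rscript analysis/03_build_networks.R    # collapsed/subset networks, C1-C4
Rscript analysis/04_compare_elements.R  # uniqueness + Jaccard matrices
Rscript analysis/05_tf_presence.R       # TF matrices + k-means clusters
Rscript analysis/06_variant_enrichment.R# empirical + Fisher variant tests
```

Output of a full run (seed 42):

```
Simulated 6 cell-type networks of 5000 enhancers each (15750 distinct elements), 6000 genes, 60 TFs.
Scored 868 candidate enhancers within 5 Mb of an example promoter; scores sum to 1.000000000000, 7 pass the 0.02 threshold
Filters kept 24678 of 38972 EPIs overall (63.3%)
Collapsed network: 24678 EPIs across 6 cell types; 12470 distinct enhancer intervals, 12470 after overlap-merging
Subset network categories (merged EPIs): Mature=1581, Progenitor=1563, NSC=1380, NPC=1370, AD=1360, Ngn2=1350, ESC=1348, Motor=1348, Removed=585, Ubi=585
Mean uniqueness: enhancers 35.0%, promoters 2.4% (planted specific fraction: 35%)
Enhancer Jaccard: within-stage mean 0.481 vs cross-stage mean 0.143
k-means (k = 3) stage clusters: higher_progenitor=20, equal=20, higher_mature=20; agreement with planted archetypes 100%
Case vs control Fisher by sub-structure (3x planted into C3):
  C3: OR = 2.217, p = 0.0002739
Empirical test (C3 enhancers vs pooled elements, R = 1000, corrected threshold 0.008333):
  ESC: observed 64 vs null mean 47.2, p = 0.002997 *
```

Reading it: the comparison module recovers the planted 35% enhancer
specificity exactly and shows promoters far less cell-type-specific than
enhancers; stage-sharing produces the within-stage Jaccard block
structure (0.48 vs 0.14); the weighted TF matrix separates the three
planted archetypes perfectly at bias 0.6; and both inferential routes
detect the planted 3× case-variant enrichment in C3 elements — the
Fisher contrast with OR ≈ 2.3 (attenuated below 3 because shared
enhancers carry several category labels), the empirical test with
p below the corrected 0.008333 threshold in most cell types.

A minimal in-R session:

```r
library(epinets)
cfg <- sim_config(seed = 1)
epi <- generate_epi_tables(cfg)
round(unique_element_fraction(epi$networks), 3)
#>   ESC   NSC   NPC    AD  Ngn2 Motor
#>  0.35  0.35  0.35  0.35  0.35  0.35
filtered <- lapply(epi$networks, filter_epis)
substructure_distribution(classify_substructure(filtered$ESC))
```

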