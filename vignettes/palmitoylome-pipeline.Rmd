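---
title: "Methods: expression analysis of the brain S-palmitoylation machinery"
author: "palmexpr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression analysis of the brain S-palmitoylation machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palmexpr)
```

## The problem

Protein S-palmitoylation — the reversible thioester attachment of palmitate
to cysteines — is written by the 24-member mouse ZDHHC acyltransferase
family, erased by a dozen thioesterases (PPT1, the APT/LYPLA enzymes and a
set of ABHD serine hydrolases), and tuned by three accessory proteins
(GOLGA7, GOLGA7B, SELENOK). Where each of these 39 genes is expressed across
brain regions and cell types constrains which substrates each enzyme can
meet. `palmexpr` implements the computational pipeline used to build and
mine such expression atlases: normalize single-cell counts, average them
into metacell profiles, correlate the enzyme panel with the transcriptome,
test candidate co-expressed genes for enrichment of annotated
palmitoylation substrates, derive region-enriched "projected palmitoylomes"
from replicate FPKM designs, compare mRNA and protein cell-type enrichment,
and quantify palmitoylation assay fractions. Because the original inputs
are multi-gigabyte accessions, the package ships a synthetic-data generator
with planted ground truth so that every stage is exercised and validated at
desk scale.

## Normalization and aggregation

Counts are normalized per cell to counts-per-10,000 before a log transform:

$$x_{gc} = \log_2\!\left(\frac{10^4\, k_{gc}}{\sum_g k_{gc}} + 1\right)$$

`cp10k_log2()` enforces the contract exactly: after the transform, the
pre-log scaled values of every retained cell sum to 10,000 (cells with zero
total count cannot be scaled and are dropped with a warning). The transform
is monotone within a cell, so within-cell expression ranking is preserved.

`aggregate_by_group()` averages normalized values within groups defined by
a cell-metadata key (metacell, region, neurotransmitter class, ...).
Normalization precedes averaging — groups are averaged on the post-log
scale. Groups with fewer than `min_cells = 5` cells are dropped, the atlas
convention for categories too small to display; the dropped groups and any
unannotated cells are reported. For droplet-atlas dialects that publish
trimmed-mean log2(CPM+1) profiles, `stat = "trimmed_mean_25_75"` computes an
interquartile trimmed mean. The published dialect names the 25–75% window
but not its rounding; we remove `floor(n/4)` observations from each end of
the sorted values, which is deterministic, symmetric, and reduces to
`mean(1, 2, 3) = 2` on the worked five-point example `0, 1, 2, 3, 100`.

Heatmap orderings come in two forms: `rank_order()` sorts rows and columns
by descending means with stable ties (the "ranked heatmap" convention), and
`hierarchical_order()` returns agglomerative-clustering leaf orders. The
published heatmaps were clustered in a GUI tool whose settings are not
recorded, so the defaults — Euclidean distance, average linkage — are
ordinary choices exposed as arguments rather than assertions about the
original.

## Co-expression

`spearman_pairs()` computes Spearman correlations between gene profiles
across groups: the Pearson correlation of average-rank (midrank)
transformed profiles. Two-sided p-values use the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n - 2$ degrees of freedom for
$n \ge 10$ groups; below that the approximation is unreliable and the
p-value is computed by exact enumeration of all $n!$ rank permutations.
Pairs involving a zero-variance profile are undefined and excluded from
the multiple-testing family. The Benjamini–Hochberg family is all defined
pairs of one `spearman_pairs()` call — correlations are adjusted within the
computed set, not across calls.

Networks (`build_network()`) use a strict threshold on signed rho
(`rho > 0.5` for the enzyme-panel network, `rho > 0.4` for the extended
panel; negative correlations never form edges), and nodes carry mean
expression across all groups. Transcriptome-wide candidate tiers
(`coexpressed_gene_set()`) collect non-panel genes with at least one panel
partner above threshold; tiers at increasing thresholds are nested by
construction. A co-expression cutoff quoted as "significant correlation
(R > 0.7)" can be read with or without an FDR filter on top; the default
applies `q < 0.05` and `q_max = NULL` reproduces the plain rho cutoff, so
either reading is available.

## Annotation enrichment

`fisher_test_2x2()` implements the two-sided exact test of a 2×2 table
from the hypergeometric point-probability rule: with margins fixed, the
p-value is the sum of point probabilities not exceeding that of the
observed table (relative tolerance $1+10^{-7}$), the convention of the
classical exact test. The odds ratio is reported as the sample $ad/bc$
estimate with a Haldane–Anscombe 0.5 correction when a cell is zero,
flagged in the result. `fisher_enrichment()` builds the table from gene
sets against an `annotation_table()`: when one set is nested in the other
(a tight co-expression tier inside a loose one, or a candidate list inside
the background universe) the comparison column is the surrounding set
minus the tested set; non-nested sets are disjointified by their symmetric
difference with the overlap reported. Whether the published tier
comparisons disjointified is not recorded; this package's convention is a
design choice, stated here, not an assertion about the original.

## Regional enrichment and projected palmitoylomes

`regional_fold_enrichment()` screens a replicate FPKM table for genes
enriched in a target region under the standard filter triple: target mean
FPKM ≥ 5, fold ≥ 1.5 (inclusive), and BH-adjusted `q < 0.05`. The fold is
computed per comparison region ("min" mode: the gene must clear the fold
against every other region, matching "enriched in each sub-region vs the
others"), with comparator means floored at ε = 0.01 to keep folds finite;
"pooled" mode compares against the pooled mean instead. The original
websites' internal differential test is undocumented, so the test here is
a two-sample t on log2(FPKM+1), target replicates versus all other
replicates pooled. The default pools the variance: with 2–3 replicates per
region, the Welch statistic has ~3 effective degrees of freedom and even a
threefold planted change often cannot reach corrected significance,
whereas multiplicative (log-scale) replicate noise in these designs is
close to homoscedastic, which is exactly the pooled-t assumption. At this
design the pooled test has 10 degrees of freedom and recovers planted
3-fold markers at better than 97% with a false-pass rate near zero;
`var_equal = FALSE` gives the Welch form for users who prefer it.
`projected_palmitoylome()` then intersects the passing genes with a
substrate annotation flag, carrying the fold statistics through.

A 20-gene fixture (installed as `extdata/synthetic_hippocampus_fpkm.tsv`,
four subfields × three replicates, all values synthetic and hand-written)
pins the filter arithmetic down to a hand enumeration. For target dCA1:

| gene | target mean | max other mean | fold | floor ≥ 5 | outcome |
|---|---|---|---|---|---|
| Wfs1 | 31 | 6 | 5.17 | yes | pass |
| Fibcd1 | 20 | 4 | 5.00 | yes | pass |
| Pou3f1 | 12 | 8 | 1.50 | yes | pass (fold boundary is inclusive) |
| Gpr161 | 26 | 11 | 2.36 | yes | pass |
| Plekha2 | 4.5 | 1.2 | 3.75 | **no** | fail floor |
| Slc17a7 | 42 | 32 | 1.31 | yes | fail fold |
| Prox1 | 5 | 52 | 0.10 | yes | fail (a dDG marker) |
| 13 others | equal means everywhere | — | 1.0 | — | fail |

Of the four passing genes, three (Wfs1, Pou3f1, Gpr161) carry the
synthetic substrate flag, so the projected palmitoylome has exactly three
members.

## mRNA–protein concordance and acyl-RAC fractions

`celltype_zscores()` standardizes each gene across cell types with the
sample (n−1) standard deviation — the published analysis does not state
the denominator, so this is recorded as the package's convention — and
drops zero-variance genes. `concordance()` pools all matched
(gene, cell type) z-score pairs and reports the Pearson correlation with
its two-sided p.

`acylrac_fractions()` evaluates the densitometry formulas verbatim:

$$\text{palm\%} = 100\,\frac{P - \text{NSB}}{(P - \text{NSB}) + U},
\qquad
\text{unpalm\%} = 100\,\frac{U}{P + U}$$

with the NSB subtraction clipped at zero. The unpalmitoylated formula, as
printed in the assay convention this package follows, omits the NSB term,
so the two percentages need not sum to 100; whether that asymmetry is
intentional cannot be determined from the text, so the formulas are
implemented verbatim and `consistent_nsb = TRUE` offers the symmetric
alternative.

## The synthetic-data generator

`simulation_spec()` fixes every generator parameter; all outputs are pure
functions of the spec (including its seed) and leave the caller's RNG
stream untouched. What it emulates, and the condition defaults:

* **Counts** (`simulate_counts()`): 265 metacell groups — the scale of the
  whole-brain atlas the co-expression analysis runs on — with 60 cells
  each (the real atlas averages hundreds of cells per metacell; 60 is a
  conservative desk-scale choice that keeps group means stable), negative
  binomial counts with per-gene size in 0.5–2 (substantial, realistic
  overdispersion; dispersions are drawn from a stated range rather than
  estimated from data, since recovery tests need only realistic
  magnitudes), log-normal library sizes (median 4,000 UMI), and per-gene
  base expression spanning log-uniform 0.05–20.
* **Planted modules**: group-level expression of module genes shares a
  Gaussian copula with latent Pearson correlation $2\sin(\pi\rho_s/6)$,
  the exact inverse of the Spearman–Pearson relation for bivariate
  normals, applied to the group means (not per-cell noise) because the
  downstream correlations are computed on metacell averages. The module
  log-sd of 1.2 makes the biological between-group spread dominate count
  sampling noise, so the rho realized by the full
  normalize–aggregate–correlate pipeline sits within ±0.05 of the target
  at the default design.
* **Annotation** (`simulate_annotation()`): a 15,000-gene universe
  (matching the brain-expressed background scale), baseline flag rate
  0.2, and an enriched set of 900 whose flag probability solves
  $p'/(1-p') = \text{OR}\cdot b/(1-b)$, so the planted odds ratio is
  exact in expectation.
* **Replicate FPKM** (`simulate_replicate_fpkm()`): four hippocampal
  subfields × 3 replicates, log-normal base FPKM (median 15), planted
  markers at 3-fold, multiplicative replicate noise with log-sd 0.25.
* **mRNA/protein pairs** (`simulate_mrna_protein()`): 150 genes × 4 cell
  types of latent bivariate-normal z-structures back-transformed to
  positive abundances by per-gene increasing affine maps (which the
  z-scoring step inverts exactly). The latent correlation is calibrated
  for small-sample attenuation: sample z-scoring over only 4 cell types
  biases the measured pooled correlation below the latent one by the
  classical factor $\approx 1-(1-\rho^2)/(2(n-1))$, so the generator
  solves that expansion for the latent value (≈ 0.69 for a measured
  target of 0.63). The calibration targets the quantity the pipeline
  actually measures.

What the generator does **not** emulate: batch effects, doublets, ambient
RNA, dropout beyond what the negative binomial induces, gene–gene
correlation outside planted modules (aside from the mild compositional
coupling that per-cell scaling introduces), or study-specific processing
quirks. Passing recovery tests therefore demonstrates that the statistics
are implemented correctly and are calibrated under clean planted truth —
not that they are robust to every artifact of real single-cell data.

## Numerical choices and degenerate inputs

* Ties: average ranks everywhere; ordering ties broken by input position
  (stable) in `rank_order()` and `substrate_candidates()`.
* Zero-variance profiles, all-zero cells, groups below `min_cells`,
  genes flagged outside the universe, and NSB exceeding the palmitoylated
  signal are all handled by drop-and-report rather than silent NA.
* Exact-test p-values compare point probabilities with a $1+10^{-7}$
  relative tolerance to absorb floating-point ties in the pmf.
* The permutation-exact Spearman path memoizes the permutation index
  matrix per $n$ ($n \le 9$, at most 362,880 rows).

## Problem sizes used by the test suite

The suite validates oracle equivalence on exhaustive small cases (every
2×2 table with total ≤ 60; 200 random tied profiles; 1,000 random
p-vectors), and the recovery properties on 10–20 seeded replicates of the
default designs above (20 × 4 regions for the regional screen, 20 seeds
of 265 metacells for module recovery, 500 + 200 draws for enrichment
calibration and power). These sizes keep the full suite under a minute
while leaving the binomial noise on every asserted rate well inside its
margin.

## Known limitations

* Gene identity is handled purely by case-canonicalized mouse symbol; no
  identifier-space translation is attempted.
* The loom reader requires `rhdf5` and reads only the dense `matrix`
  layout with a `Gene` row attribute.
* The regional differential test is a per-gene two-sample t; no
  moderation across genes (as limma would do) is applied, by design, to
  keep the filter triple transparent.
* The exact Spearman path enumerates permutations and is only used (and
  only feasible) below 10 groups.
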