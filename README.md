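# palmexpr

Expression analysis of the proteins that regulate S-palmitoylation in the
mouse brain, as a tested, reusable R pipeline.

S-palmitoylation — reversible attachment of palmitate to protein cysteines
— is written by the 24 mouse ZDHHC acyltransferases, erased by 12
de-palmitoylating enzymes (PPT1, LYPLA1/2, and the ABHD hydrolases), and
modulated by 3 accessory proteins (GOLGA7, GOLGA7B, SELENOK). Mapping
where these 39 genes are expressed across brain cell types, which other
genes they are co-expressed with, and whether those co-expressed genes are
enriched for annotated palmitoylation substrates is how candidate
enzyme–substrate pairs are generated from transcriptomic atlases. This
package implements that whole analysis for anyone who wants to run it on
their own expression matrices — or on the package's synthetic data with
planted ground truth.

## What it computes

* **Normalization / aggregation** — per-cell counts-per-10,000 log
  normalization, `x = log2(1e4 · k / colsum + 1)`, then group averaging
  into metacell/cluster/region profiles with a minimum-cell filter
  (groups under 5 cells are dropped), including the trimmed-mean
  (25–75%) dialect; ranked and hierarchically clustered orderings for
  heatmaps.
* **Co-expression** — pairwise Spearman ρ across group profiles (average
  ranks; two-sided p by t approximation for n ≥ 10 groups, exact
  permutation enumeration below), Benjamini–Hochberg q within each
  computed family; networks at ρ > 0.5 / ρ > 0.4 and transcriptome tiers
  co-expressed with the panel at ρ > 0.7 / ρ > 0.8.
* **Substrate enrichment** — two-sided exact 2×2 test computed from the
  hypergeometric point-probability rule, sample odds ratio with
  Haldane–Anscombe correction, annotated proportions, ranked substrate
  candidate lists.
* **Projected palmitoylomes** — region-enriched genes from replicate FPKM
  tables under the filter triple fold ≥ 1.5, mean FPKM ≥ 5, q < 0.05,
  intersected with a substrate annotation flag.
* **mRNA–protein concordance** — per-gene cell-type z-scores
  (sample sd), pooled Pearson correlation across all matched pairs.
* **Acyl-RAC quantification** — the palmitoylated / unpalmitoylated
  fraction formulas, `100·(P−NSB)/((P−NSB)+U)` and `100·U/(P+U)`,
  evaluated verbatim.
* **Synthetic data** — negative-binomial single-cell counts over 265
  metacells with copula-planted co-expression modules, annotation flags
  with a planted odds ratio, replicate FPKM tables with planted regional
  markers, and paired mRNA/protein abundances at a target concordance.

Input formats: dense TSV and Matrix Market MTX (plus loom via `rhdf5`) for
count matrices, TSV for metadata, panels, annotation lists and replicate
FPKM tables (two-row region/replicate header). All writers emit TSV;
networks also export GraphML.

## Worked example

The `analysis/` scripts run the full pipeline on synthetic data, in order:

```sh
Rscript analysis/01_simulate.R            # inputs with planted truth
Rscript analysis/02_normalize_aggregate.R # CP10K + metacell profiles
Rscript analysis/03_coexpression.R        # Spearman networks and tiers
Rscript analysis/04_enrichment.R          # substrate enrichment test
Rscript analysis/05_regional_palmitoylome.R
Rscript analysis/06_concordance_acylrac.R
```

Output from a run (planted truth in parentheses):

```
counts: 120 genes x 15900 cells in 265 metacells
panel pairs: mean rho 0.862 (planted 0.9)
panel network at rho > 0.5: 5 nodes, 10 edges
flagged: 44.6% of the planted set vs 21.8% of the universe
enrichment: OR 3.14 (planted 3), two-sided p 1.18e-55
random set of equal size: OR 0.92, p 0.360
dCA1: 11 genes pass (recall of 10 planted markers: 1.00)
mRNA-protein concordance: r = 0.674 (target 0.63), p = 7.7e-81 over 600 pairs
acyl-RAC worked example (P=8, U=4, NSB=2): palm 60.0%, unpalm 33.33%
```

The five panel genes planted as a ρ = 0.9 module are recovered with all
ten pairwise edges above the ρ > 0.5 network threshold; the planted
annotation odds ratio, regional markers, and mRNA–protein concordance are
all recovered at their planted values, and the acyl-RAC formulas reproduce
the hand-computed 60% / 33.33% split. Tables land under `results/`.

## Layout

```
R/                  package functions (all computation lives here)
analysis/           numbered narrative drivers over the package
inst/extdata/       small synthetic text fixtures (hand-enumerable)
tests/testthat/     unit, property and acceptance tests with
                    brute-force oracles
scripts/acceptance.R
vignettes/palmitoylome-pipeline.Rmd   methods notes
```
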