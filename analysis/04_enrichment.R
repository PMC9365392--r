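#!/usr/bin/env Rscript
# Test the planted substrate annotation: proportion flagged in the planted
# enriched set, exact-test enrichment against the background universe, and
# the null behaviour of an unenriched draw of the same size.

suppressPackageStartupMessages(library(palmexpr))

ann <- read_annotation_table(
  "results/data/annotation.universe.tsv",
  c(substrate = "results/data/annotation.substrate.tsv"))
enriched <- readLines("results/data/planted_enriched.tsv")

prop <- annotation_proportion(enriched, ann, "substrate")
bg <- annotation_proportion(ann$universe, ann, "substrate")
message(sprintf("flagged: %.1f%% of the planted set vs %.1f%% of the universe",
                100 * prop$proportion, 100 * bg$proportion))

res <- fisher_enrichment(enriched, ann$universe, ann, "substrate")
message(sprintf("enrichment: OR %.2f (planted 3), two-sided p %.3g",
                res$odds_ratio, res$p_two_sided))

set.seed(20260919)
random_set <- sample(ann$universe, length(enriched))
null_res <- fisher_enrichment(random_set, ann$universe, ann, "substrate")
message(sprintf("random set of equal size: OR %.2f, p %.3f",
                null_res$odds_ratio, null_res$p_two_sided))

out <- list(
  planted = list(proportion = prop$proportion, odds_ratio = res$odds_ratio,
                 p = res$p_two_sided, table = as.data.frame(res$table)),
  random = list(odds_ratio = null_res$odds_ratio, p = null_res$p_two_sided))
jsonlite::write_json(out, "results/enrichment.json", auto_unbox = TRUE,
                     pretty = TRUE, digits = NA)
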