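#!/usr/bin/env Rscript
# Generate every input the pipeline consumes, with planted ground truth:
# a 265-metacell single-cell count matrix carrying a 5-gene co-expression
# module at Spearman 0.9 on the panel genes Zdhhc3/8/17/21 + Golga7b, a
# 15,000-gene substrate annotation with a planted odds ratio of 3, a
# four-subfield replicate FPKM table with 3-fold regional markers, and
# paired mRNA/protein abundances at target concordance 0.63.

suppressPackageStartupMessages(library(palmexpr))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

panel_module <- c("Zdhhc3", "Zdhhc8", "Zdhhc17", "Zdhhc21", "Golga7b")
gene_names <- c(panel_module, sprintf("Gene%04d", 6:120))
spec <- simulation_spec(
  seed = 20260919L,
  gene_names = gene_names,
  modules = list(list(genes = panel_module, rho = 0.9)))

sim <- simulate_counts(spec)
write_count_matrix(sim$counts, file.path(out, "counts.tsv"))
write.table(sim$meta, file.path(out, "cell_meta.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("counts: ", length(sim$counts$genes), " genes x ",
        length(sim$counts$cells), " cells in ",
        length(unique(sim$meta$metacell)), " metacells")

ann <- simulate_annotation(spec)
write_annotation_table(ann, file.path(out, "annotation"))
writeLines(attr(ann, "enriched_genes"), file.path(out, "planted_enriched.tsv"))
message("annotation: universe ", length(ann$universe), ", flagged ",
        length(ann$flags$substrate))

fpkm <- simulate_replicate_fpkm(simulation_spec(seed = 20260919L,
                                                n_genes = 200L))
write_replicate_matrix(fpkm, file.path(out, "hippocampus_fpkm.tsv"))
for (r in names(attr(fpkm, "markers"))) {
  writeLines(attr(fpkm, "markers")[[r]],
             file.path(out, paste0("planted_markers_", r, ".tsv")))
}

ab <- simulate_mrna_protein(spec)
for (nm in names(ab)) {
  write.table(data.frame(gene = rownames(ab[[nm]]), ab[[nm]]),
              file.path(out, paste0(nm, "_abundance.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
message("wrote all synthetic inputs under ", out)
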