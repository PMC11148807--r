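#!/usr/bin/env Rscript
# Generate every synthetic dataset the downstream analyses use, with planted
# ground truth, and write them in the standard on-disk formats.

suppressPackageStartupMessages(library(scmodkit))

out <- "scratch/data"   # bulky regenerable inputs; summary tables go to results/
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## Droplet mixture: 60% nuclei (3 cell types), 30% empty, 10% contaminated
cfg <- droplet_sim_config(seed = 1)
ds <- generate_droplet_dataset(cfg)
write_mtx_dir(list(spliced = ds$spliced, unspliced = ds$unspliced),
              file.path(out, "droplets"))
write_gene_sets(ds$gene_sets, file.path(out, "gene_sets.tsv"))
jsonlite::write_json(ds$truth[c("droplet_class", "celltype")],
                     file.path(out, "droplet_truth.json"))
cat("droplets:", nrow(ds$spliced), "x", ncol(ds$spliced),
    "| class mix:", paste(names(table(ds$truth$droplet_class)),
                          table(ds$truth$droplet_class), collapse = " "), "\n")

## Module-structured counts: 4 planted 20-gene modules, loading 0.8
mcfg <- module_sim_config(seed = 1)
msim <- generate_module_dataset(mcfg)
write_mtx_dir(msim$matrix, file.path(out, "module_counts"))
jsonlite::write_json(list(module_of_gene = msim$truth$module_of_gene),
                     file.path(out, "module_truth.json"))
cat("module matrix:", nrow(msim$matrix), "cells x", ncol(msim$matrix),
    "genes;", sum(!is.na(msim$truth$module_of_gene)), "genes in modules\n")

## Two spatial sections, each with two segregated expression territories
genes_a <- paste0("ga", 1:8)
genes_b <- paste0("gb", 1:8)
domains <- list(
  list(type = "disc", center = c(300, 400), radius = 250,
       profile = stats::setNames(rep(1, 8), genes_a)),
  list(type = "disc", center = c(900, 400), radius = 250,
       profile = stats::setNames(rep(1, 8), genes_b)))
for (i in 1:2) {
  sl <- generate_molecule_table(1200, 800, domains, 10000, seed = i,
                                section = paste0("S", i))
  write_molecule_csv(sl$molecules, file.path(out, sprintf("molecules_S%d.csv", i)))
}
cat("molecule tables: 2 sections x 10000 molecules on 1200x800 px\n")

## Paired DE tables with known overlap and logFC correlation
de <- generate_de_comparison(n_genes = 2000, shared_fraction = 2 / 3,
                             logfc_correlation = 0.9, seed = 1, n_sig = 1500)
utils::write.table(de$table_a, file.path(out, "de_table_a.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(de$table_b, file.path(out, "de_table_b.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("DE tables: expected Jaccard", de$expected_jaccard, "\n")
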