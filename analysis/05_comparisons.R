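#!/usr/bin/env Rscript
# Figure-level comparison statistics: Jaccard similarity of DEG sets, logFC
# correlations of the paired DE tables, per-sample cell-type proportions with
# group boxplot summaries, and a 0-1 scaled mean profile.

suppressPackageStartupMessages(library(scmodkit))

data_dir <- "scratch/data"
out <- "results"
ta <- utils::read.delim(file.path(data_dir, "de_table_a.tsv"))
tb <- utils::read.delim(file.path(data_dir, "de_table_b.tsv"))

jac <- jaccard_index(ta$gene[ta$significant], tb$gene[tb$significant])
ovl <- logfc_correlation(ta, tb, mode = "overlap_significant")
alg <- logfc_correlation(ta, tb, mode = "all_genes")
cat(sprintf("DEG Jaccard %.3f; logFC r (overlap) %.3f over %d genes; (all) %.3f over %d\n",
            jac, ovl$r, ovl$n, alg$r, alg$n))

## per-sample cell-type proportions from the droplet simulation truth,
## split into two pseudo-samples per group
truth <- jsonlite::read_json(file.path(data_dir, "droplet_truth.json"),
                             simplifyVector = TRUE)
nuclei <- !is.na(truth$celltype)
celltype <- truth$celltype[nuclei]
set.seed(1)
samples <- sample(paste0("s", 1:4), sum(nuclei), replace = TRUE)
groups <- c(s1 = "ctrl", s2 = "ctrl", s3 = "hf", s4 = "hf")
pr <- compute_proportions(celltype, samples, groups)
utils::write.table(pr, file.path(out, "celltype_proportions.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
gs <- attr(pr, "group_summaries")
utils::write.table(gs, file.path(out, "proportion_summaries.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cm <- pr$proportion[pr$label == "nucleus_CM"]
cat(sprintf("nucleus_CM proportion across samples: %.1f-%.1f%% (median %.1f%%)\n",
            min(cm), max(cm), stats::median(cm)))

## 0-1 scaled mean marker-score profile across cell types
means <- tapply(pr$proportion, pr$label, mean)
scaled <- minmax_scale(as.numeric(means))
utils::write.table(data.frame(label = names(means), mean_pct = as.numeric(means),
                              scaled = scaled),
                   file.path(out, "scaled_mean_proportions.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("scaled mean proportions:",
    paste(sprintf("%s=%.2f", names(means), scaled), collapse = ", "), "\n")
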