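#!/usr/bin/env Rscript

# Step 3: expression analysis — normalisation, progenitor-vs-mature
# differential expression, temporal clustering of the astro lineage, PCA
# of all samples, and the coupling between stage-unique enhancers and
# own-stage expression of their nearest genes.

suppressPackageStartupMessages(library(astroprime))

out_dir <- "results"
ds <- readRDS(file.path(out_dir, "dataset.rds"))
chrom <- readRDS(file.path(out_dir, "chromatin.rds"))

expr <- ds$expression
norm <- normalize_log2(expr$counts)
stage_expr <- vapply(unique(expr$design$stage), function(s) {
  rowMeans(norm[, expr$design$sample[expr$design$stage == s], drop = FALSE])
}, numeric(nrow(norm)))

de <- de_test(expr$counts,
              expr$design$sample[expr$design$stage == "aNPC"],
              expr$design$sample[expr$design$stage == "lA"])
cat("differential genes (aNPC vs lA, FDR 0.1):", sum(de$de), "\n")
utils::write.table(de, file.path(out_dir, "de_progenitor_vs_late.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

tc <- temporal_clusters(stage_expr[, c("ESC", "aNPC", "eA", "lA")], k = 5,
                        seed = 1)
cat("temporal cluster sizes:\n")
print(table(tc$assignments))
utils::write.table(
  data.frame(gene = names(tc$assignments), cluster = unname(tc$assignments)),
  file.path(out_dir, "temporal_clusters.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

pca <- pca_samples(expr$counts)
utils::write.table(
  data.frame(sample = rownames(pca$coords), pca$coords),
  file.path(out_dir, "pca_samples.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

coupling <- expression_coupling(chrom$unique_sets$astro, ds$annotation,
                                stage_expr)
for (s in names(coupling)) {
  cat(sprintf("coupling %s: n=%d own=%.2f other=%.2f p=%.3g\n", s,
              length(coupling[[s]]$genes), coupling[[s]]$median_own,
              coupling[[s]]$median_other, coupling[[s]]$p))
}
saveRDS(list(stage_expr = stage_expr, de = de, temporal = tc, pca = pca,
             coupling = coupling),
        file.path(out_dir, "expression.rds"))
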