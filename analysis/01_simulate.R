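#!/usr/bin/env Rscript

# Step 1: simulate the synthetic differentiation dataset (genome, planted
# enhancers, ChIP tracks, expression, knockdowns) at the default scale and
# save it for the downstream analysis steps.

suppressPackageStartupMessages(library(astroprime))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

cfg <- sim_config(seed = 1L)
ds <- simulate_dataset(cfg)
saveRDS(ds, file.path(out_dir, "dataset.rds"))

write_gene_table(ds$gene_table, file.path(out_dir, "gene_table.tsv"))
utils::write.table(ds$truth, file.path(out_dir, "enhancer_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_pwms(ds$pwms, file.path(out_dir, "pwms.txt"))

cat("chromosomes:", length(ds$genome), "\n")
cat("genes:", nrow(ds$gene_table), "\n")
cat("enhancers:", nrow(ds$truth), "\n")
cat("classes:\n")
print(table(ds$truth$class))
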