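#!/usr/bin/env Rscript

# Step 5: knockdown analysis — for each simulated TF knockdown, quantify
# the acetylation change at its motif-bearing stage-unique sites, find
# deregulated genes, link them to depleted sites, and test the overlap of
# the two remodeling factors' downregulated gene sets.

suppressPackageStartupMessages({
  library(astroprime)
  library(GenomicRanges)
})

out_dir <- "results"
ds <- readRDS(file.path(out_dir, "dataset.rds"))
chrom <- readRDS(file.path(out_dir, "chromatin.rds"))

deg_sets <- list()
for (tf in names(ds$knockdowns)) {
  kd <- ds$knockdowns[[tf]]
  tfr <- ds$tf_table[ds$tf_table$tf_gene == tf, ]
  su <- chrom$unique_sets$astro[[kd$stage]]
  sites <- target_sites(su, ds$pwms[[tfr$motif_id]], ds$genome,
                        ds$thresholds[[tfr$motif_id]])
  eff <- kd_chromatin_effect(kd$control_track, kd$kd_track, ds$input, sites)
  ctrl <- kd$design$sample[kd$design$condition == "control"]
  deg <- kd_deregulated_genes(kd$counts, ctrl,
                              setdiff(kd$design$sample, ctrl))
  deg_sets[[tf]] <- deg
  cat(sprintf(
    "%s (%s, remodeling=%s): %d sites, median delta %.3f (p %.3g), %d down / %d up\n",
    tf, kd$stage, kd$remodeling, length(sites), eff$median_delta, eff$p,
    length(deg$down), length(deg$up)))
}

rem <- ds$tf_table$tf_gene[ds$tf_table$remodeling]
both <- ds$truth$linked_gene[
  vapply(strsplit(ds$truth$motifs, ","), function(m)
    all(c("M_eA1", "M_eA2") %in% m), logical(1))]
both <- both[!is.na(both)]
ov <- coregulation_overlap(deg_sets[[rem[1]]]$down, deg_sets[[rem[2]]]$down,
                           rownames(ds$expression$counts), both)
cat(sprintf("co-downregulated overlap: %d genes (p %.3g), %d co-bound\n",
            ov$overlap, ov$p, ov$co_bound))
utils::write.table(
  data.frame(gene = ov$overlap_genes,
             co_bound = ov$overlap_genes %in% both),
  file.path(out_dir, "co_downregulated_genes.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
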