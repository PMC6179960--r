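#!/usr/bin/env Rscript

# Step 4: motif enrichment in the stage-unique active enhancer sets of
# both lineages against GC-matched backgrounds, and nomination of
# candidate stage-specific transcription factors.

suppressPackageStartupMessages({
  library(astroprime)
  library(GenomicRanges)
})

out_dir <- "results"
ds <- readRDS(file.path(out_dir, "dataset.rds"))
chrom <- readRDS(file.path(out_dir, "chromatin.rds"))
expr <- readRDS(file.path(out_dir, "expression.rds"))
stages <- list(astro = c("aNPC", "eA", "lA"), neuro = c("nNPC", "eN", "lN"))

# candidate background pool: enhancer-free stretches of the gene units
set.seed(104)
unit_start <- ds$gene_table$start - 2000L
pool <- GRanges(ds$gene_table$chrom,
                IRanges(unit_start + 13000L +
                          round(runif(nrow(ds$gene_table), 0, 5400)),
                        width = 600L))

enrich <- list()
for (lin in names(stages)) {
  enrich[[lin]] <- lapply(setNames(stages[[lin]], stages[[lin]]),
                          function(s) {
    targets <- chrom$unique_sets[[lin]][[s]]
    bg <- gc_matched_background(targets, pool, ds$genome, ratio = 2,
                                seed = 1)
    res <- motif_enrichment(targets, bg, ds$genome, ds$pwms,
                            thresholds = ds$thresholds)
    utils::write.table(res, file.path(out_dir,
                                      paste0("motif_enrichment_", lin, "_",
                                             s, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res
  })
}

for (j in 1:3) {
  sa <- stages$astro[j]
  nom <- nominate_tfs(enrich$astro[[sa]], enrich$neuro[[stages$neuro[j]]],
                      ds$motif2tf, expr$stage_expr, sa)
  cat(sprintf("stage %s: common motifs [%s]; candidates [%s]\n", sa,
              paste(nom$common, collapse = ", "),
              paste(nom$candidates$tf_gene, collapse = ", ")))
}
saveRDS(enrich, file.path(out_dir, "motif_enrichment.rds"))
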