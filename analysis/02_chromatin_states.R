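#!/usr/bin/env Rscript

# Step 2: call peaks on every ChIP track, derive stage-unique active
# enhancer sets, build consensus regions, assign per-stage chromatin
# states and priming-to-activation trajectories, and cluster the regions.

suppressPackageStartupMessages({
  library(astroprime)
  library(GenomicRanges)
})

out_dir <- "results"
ds <- readRDS(file.path(out_dir, "dataset.rds"))
stages <- list(astro = c("aNPC", "eA", "lA"), neuro = c("nNPC", "eN", "lN"))

peaks <- lapply(ds$chip, call_peaks, fdr = 0.05, min_log2fc = 1)
for (cond in names(peaks)) {
  write_bed(peaks[[cond]],
            file.path(out_dir, paste0("peaks_", gsub("/", "_", cond),
                                      ".bed")))
}

unique_sets <- list()
for (lin in names(stages)) {
  sets <- setNames(lapply(stages[[lin]],
                          function(s) peaks[[paste0("H3K27ac/", s)]]),
                   stages[[lin]])
  unique_sets[[lin]] <- lapply(stage_unique_sets(sets), `[[`, "unique")
}
cat("stage-unique active set sizes:\n")
print(vapply(unlist(unique_sets, recursive = FALSE), length, integer(1)))

regions <- reduce(suppressWarnings(do.call(c, unname(peaks))),
                  ignore.strand = TRUE)
sig <- enrichment_matrix(regions, ds$chip, ds$input)
marked <- list()
for (mark in c("H3K4me1", "H3K27ac")) {
  marked[[mark]] <- lapply(stages, function(ss) {
    sub <- sig[, paste(mark, ss, sep = "/"), drop = FALSE]
    attr(sub, "kind") <- "log2_enrichment"
    m <- marked_status(sub, threshold = 1)
    colnames(m) <- ss
    m
  })
}
traj <- build_trajectories(marked$H3K4me1, marked$H3K27ac)
cl <- cluster_trajectories(sig, k = 8, seed = 1,
                           silhouette = length(regions) <= 5000)
cat("regions:", length(regions), " clusters: k =", cl$k,
    " silhouette =", round(cl$silhouette, 3), "\n")
cat("astro activation stages (primed-then-activated regions):\n")
print(table(traj$activation_stage_astro, useNA = "ifany"))

out <- cbind(traj, cluster = unname(cl$assignments),
             annotation = as.character(annotate_region(regions,
                                                       ds$annotation)))
utils::write.table(out, file.path(out_dir, "trajectories.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
saveRDS(list(peaks = peaks, unique_sets = unique_sets, regions = regions,
             signal = sig, trajectories = traj, clusters = cl),
        file.path(out_dir, "chromatin.rds"))
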