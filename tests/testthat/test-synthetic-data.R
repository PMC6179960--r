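test_that("sim_config validates its geometry and effect sizes", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_genes = 1201L), "multiple")
  expect_error(sim_config(n_genes = 1200L, chrom_len = 1e6), "fit")
  expect_error(sim_config(n_per_class = 200L), "8 \\* n_per_class")
  expect_error(sim_config(enrichment_fold_active = 1), "folds")
  expect_error(sim_config(kd_effect = 1.2), "kd_effect")
  expect_error(sim_config(kd_expr_effect = 0), "kd_expr_effect")
  expect_error(sim_config(cobound_targets = 151L), "cobound")
})

test_that("simulate_genome lays out one gene per 20-kb unit deterministically", {
  cfg <- sim_config(seed = 3L, n_chroms = 2L, chrom_len = 1.3e6,
                    n_genes = 128L, n_per_class = 16L,
                    cobound_targets = 6L)
  sim <- simulate_genome(cfg)
  expect_length(sim$genome, 2)
  expect_equal(unname(Biostrings::width(sim$genome)), rep(1.3e6, 2))
  expect_equal(nrow(sim$gene_table), 128)
  expect_false(anyDuplicated(sim$gene_table$gene_id) > 0)
  # genes sit inside their unit and exons inside the gene
  off <- (sim$gene_table$start - 1) %% 20000
  expect_true(all(off == 2000))
  expect_true(all(sim$gene_table$end - sim$gene_table$start == 2399))
  expect_identical(sim$units$tss,
                   ifelse(sim$units$strand == "+", sim$gene_table$start,
                          sim$gene_table$end))
  sim2 <- simulate_genome(cfg)
  expect_identical(as.character(sim$genome), as.character(sim2$genome))
  expect_identical(sim$gene_table, sim2$gene_table)
})

test_that("plant_enhancers places linked enhancers 5-7.5 kb from the TSS", {
  ds <- small_dataset()
  truth <- ds$truth
  expect_equal(unname(table(truth$class)[c(
    "aNPC_unique", "eA_unique", "lA_unique", "nNPC_unique", "eN_unique",
    "lN_unique", "constitutive", "never_active")]), rep(20L, 8),
    ignore_attr = TRUE)
  expect_true(all(truth$tss_dist >= 5000 & truth$tss_dist <= 7500))
  linked <- !is.na(truth$linked_gene)
  expect_true(all(linked == (truth$class %in%
    c("aNPC_unique", "eA_unique", "lA_unique", "nNPC_unique",
      "eN_unique", "lN_unique"))))
  # the linked gene is the region's nearest TSS under the assignment rule
  gr <- GRanges(truth$chrom[linked],
                IRanges(truth$start[linked], truth$end[linked]))
  got <- assign_nearest_gene(gr, ds$annotation)
  expect_identical(got, truth$linked_gene[linked])
})

test_that("planted truth obeys priming-before-activation and shared progenitors", {
  truth <- small_dataset()$truth
  for (lin in c("astro", "neuro")) {
    stages <- if (lin == "astro") c("aNPC", "eA", "lA") else
      c("nNPC", "eN", "lN")
    st <- as.matrix(truth[, paste(lin, stages, sep = "_")])
    active2 <- st[, 2] == "active"
    active3 <- st[, 3] == "active"
    # newly active elements were primed or active at the preceding stage
    expect_true(all(st[active2, 1] %in% c("primed", "active")))
    expect_true(all(st[active3, 2] %in% c("primed", "active")))
  }
  # both progenitors share chromatin except at neuro-lineage classes
  shared <- !(truth$class %in% c("nNPC_unique", "eN_unique", "lN_unique"))
  expect_identical(truth$astro_aNPC[shared], truth$neuro_nNPC[shared])
})

test_that("planted motif instances pass their calibrated thresholds in situ", {
  ds <- small_dataset()
  truth <- ds$truth
  with_motif <- truth[nzchar(truth$motifs), ]
  idx <- seq(1, nrow(with_motif), by = 7)  # spot-check a subset
  for (i in idx) {
    gr <- GRanges(with_motif$chrom[i],
                  IRanges(with_motif$start[i], with_motif$end[i]))
    for (m in strsplit(with_motif$motifs[i], ",")[[1]]) {
      expect_true(region_hits(ds$pwms[[m]], gr, ds$genome,
                              ds$thresholds[[m]]),
                  label = paste("motif", m, "in", with_motif$enh_id[i]))
    }
  }
})

test_that("the co-bound split among eA enhancers matches the config", {
  ds <- small_dataset()
  truth <- ds$truth
  ms <- strsplit(truth$motifs[truth$class == "eA_unique"], ",")
  n_both <- sum(vapply(ms, function(m)
    all(c("M_eA1", "M_eA2") %in% m), logical(1)))
  expect_equal(n_both, 8)  # cobound_targets of the small config
  expect_true(all(lengths(ms) %in% 1:2))
})

test_that("simulate_chip elevates exactly the marked enhancers", {
  ds <- small_dataset()
  cfg <- ds$cfg
  truth <- ds$truth
  tr <- ds$chip[["H3K27ac/eA"]]
  expect_lt(abs(tr$library_size - cfg$chip_depth) /
              cfg$chip_depth, 0.01)
  act <- truth$astro_eA == "active"
  gr_on <- GRanges(truth$chrom[act], IRanges(truth$start[act],
                                             truth$end[act]))
  gr_off <- GRanges(truth$chrom[!act], IRanges(truth$start[!act],
                                               truth$end[!act]))
  dens_on <- mean(quantify(tr, gr_on)) / cfg$enhancer_width
  dens_off <- mean(quantify(tr, gr_off)) / cfg$enhancer_width
  expect_gt(dens_on / dens_off, cfg$enrichment_fold_active * 0.7)
  # determinism
  tr2 <- simulate_chip(cfg, truth, "H3K27ac", "eA", "astro")
  expect_identical(tr2$counts, tr$counts)
})

test_that("simulate_expression boosts linked genes at their active stages", {
  ds <- small_dataset()
  expr <- ds$expression
  expect_identical(dim(expr$counts),
                   c(nrow(ds$gene_table), 7L * ds$cfg$n_reps))
  expect_identical(colnames(expr$counts), expr$design$sample)
  truth <- ds$truth
  ea_genes <- truth$linked_gene[truth$class == "eA_unique"]
  ratio <- expr$mu[ea_genes, "eA"] / expr$mu[ea_genes, "aNPC"]
  expect_equal(unname(ratio), rep(ds$cfg$expr_boost, length(ea_genes)))
  # deterministic
  expr2 <- simulate_expression(ds$cfg, list(
    gene_table = ds$gene_table, truth = ds$truth, motif2tf = ds$motif2tf))
  expect_identical(expr2$counts, expr$counts)
})

test_that("remodeling knockdowns lose the configured H3K27ac fraction", {
  ds <- small_dataset()
  cfg <- ds$cfg
  kd <- ds$knockdowns$Tfa
  expect_true(kd$remodeling)
  tgt <- ds$truth[ds$truth$enh_id %in% kd$target_enhancers, ]
  gr <- GRanges(tgt$chrom, IRanges(tgt$start, tgt$end))
  ratio <- sum(quantify(kd$kd_track, gr)) / sum(quantify(kd$control_track,
                                                         gr))
  expect_lt(abs(ratio - cfg$kd_effect), 0.08)
  # non-remodeling knockdown leaves chromatin untouched
  kdc <- ds$knockdowns$Tfc
  expect_false(kdc$remodeling)
  tgtc <- ds$truth[ds$truth$enh_id %in% kdc$target_enhancers, ]
  grc <- GRanges(tgtc$chrom, IRanges(tgtc$start, tgtc$end))
  ratio_c <- sum(quantify(kdc$kd_track, grc)) /
    sum(quantify(kdc$control_track, grc))
  expect_lt(abs(ratio_c - 1), 0.1)
  # expression of target genes drops by kd_expr_effect in expectation
  expect_identical(colnames(kd$counts), kd$design$sample)
  ctrl_mean <- rowMeans(kd$counts[kd$target_genes, 1:3])
  kd_mean <- rowMeans(kd$counts[kd$target_genes, 4:6])
  expect_lt(median(kd_mean / ctrl_mean), 2 * cfg$kd_expr_effect)
  expect_error(simulate_knockdown(cfg, ds, "nope"), "unknown TF")
})

test_that("simulate_dataset is reproducible end to end", {
  cfg <- sim_config(seed = 12L, n_chroms = 2L, chrom_len = 1.7e6,
                    n_genes = 160L, n_per_class = 20L,
                    cobound_targets = 8L, chip_depth = 4e5)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$expression$counts, b$expression$counts)
  expect_identical(a$chip[["H3K4me1/lA"]]$counts,
                   b$chip[["H3K4me1/lA"]]$counts)
  expect_identical(a$knockdowns$Tfb$counts, b$knockdowns$Tfb$counts)
  # a different seed changes the draws
  cfg2 <- sim_config(seed = 13L, n_chroms = 2L, chrom_len = 1.7e6,
                     n_genes = 160L, n_per_class = 20L,
                     cobound_targets = 8L, chip_depth = 4e5)
  c_ <- simulate_dataset(cfg2)
  expect_false(identical(a$expression$counts, c_$expression$counts))
})
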