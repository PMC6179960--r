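#' Default end-to-end pipeline configuration
#'
#' Analysis parameters for [run_pipeline()]: the simulation seed and depth,
#' peak calling and marking cutoffs, clustering sizes, motif calibration and
#' background matching, and the differential-expression FDR levels.
#'
#' @return named list of parameters.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    stages_astro = c("aNPC", "eA", "lA"),
    stages_neuro = c("nNPC", "eN", "lN"),
    n_chroms = 4L,
    chrom_len = 6.2e6,
    n_genes = 1200L,
    n_per_class = 150L,
    cobound_targets = 47L,
    bin_size = 200L,
    chip_depth = 2e6,
    peak_fdr = 0.05,
    peak_min_log2fc = 1,
    marked_threshold = 1,
    min_overlap_bp = 1L,
    max_tss_dist = 50000L,
    de_fdr = 0.1,
    kd_fdr = 0.1,
    n_region_clusters = 8L,
    n_temporal_clusters = 5L,
    motif_pvalue = 1e-4,
    background_ratio = 2,
    gc_bins = 10L
  )
}

#' Validate a pipeline configuration
#'
#' Checks a (possibly partial) configuration against the keys of
#' [default_config()]: unknown keys, non-positive or out-of-range numbers,
#' and stage lists that are not exactly three stage names.
#'
#' @param config named list of parameters.
#' @return character vector of violations; empty when the config is valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  if (!is.list(config) || (length(config) && is.null(names(config)))) {
    return("config must be a named list")
  }
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) {
    v <- c(v, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  one_number <- function(key) {
    key %in% names(config) &&
      (!is.numeric(config[[key]]) || length(config[[key]]) != 1 ||
         !is.finite(config[[key]]))
  }
  for (key in c("seed", "n_chroms", "chrom_len", "n_genes", "n_per_class",
                "cobound_targets", "bin_size", "chip_depth", "peak_fdr",
                "peak_min_log2fc", "marked_threshold", "min_overlap_bp",
                "max_tss_dist", "de_fdr", "kd_fdr", "n_region_clusters",
                "n_temporal_clusters", "motif_pvalue", "background_ratio",
                "gc_bins")) {
    if (one_number(key)) v <- c(v, paste0(key, " must be a single number"))
  }
  pos <- function(key) {
    key %in% names(config) && !one_number(key) && config[[key]] <= 0
  }
  for (key in c("n_chroms", "chrom_len", "n_genes", "n_per_class",
                "cobound_targets", "bin_size", "chip_depth",
                "min_overlap_bp", "max_tss_dist", "background_ratio",
                "gc_bins", "peak_min_log2fc")) {
    if (pos(key)) v <- c(v, paste0(key, " must be > 0"))
  }
  for (key in c("peak_fdr", "de_fdr", "kd_fdr", "motif_pvalue")) {
    if (key %in% names(config) && !one_number(key) &&
        (config[[key]] <= 0 || config[[key]] >= 1)) {
      v <- c(v, paste0(key, " must be in (0, 1)"))
    }
  }
  for (key in c("n_region_clusters", "n_temporal_clusters")) {
    if (key %in% names(config) && !one_number(key) && config[[key]] < 2) {
      v <- c(v, paste0(key, " must be >= 2"))
    }
  }
  if ("seed" %in% names(config) && !one_number("seed") &&
      (config$seed != round(config$seed) || abs(config$seed) >= 2^31)) {
    v <- c(v, "seed must be an integer below 2^31 in magnitude")
  }
  for (key in c("stages_astro", "stages_neuro")) {
    if (key %in% names(config) &&
        (!is.character(config[[key]]) || length(config[[key]]) != 3 ||
           any(!nzchar(config[[key]])) || anyDuplicated(config[[key]]))) {
      v <- c(v, paste0(key, " must be 3 distinct stage names"))
    }
  }
  v
}

# Fraction of query regions overlapping the subject set, and vice versa.
overlap_precision_recall <- function(called, truth_gr) {
  if (length(called) == 0) {
    return(list(precision = NA_real_, recall = 0, n_called = 0L,
                n_truth = length(truth_gr)))
  }
  list(
    precision = mean(IRanges::overlapsAny(called, truth_gr,
                                                ignore.strand = TRUE)),
    recall = mean(IRanges::overlapsAny(truth_gr, called,
                                             ignore.strand = TRUE)),
    n_called = length(called), n_truth = length(truth_gr)
  )
}

# Map consensus regions to the truth enhancer they overlap (NA when none
# or ambiguous).
match_truth_class <- function(regions, truth_gr, classes) {
  hits <- GenomicRanges::findOverlaps(regions, truth_gr,
                                      ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  out <- rep(NA_character_, length(regions))
  single <- names(which(table(q) == 1))
  keep <- q %in% as.integer(single)
  out[q[keep]] <- classes[S4Vectors::subjectHits(hits)[keep]]
  out
}

#' Run the full synthetic differentiation analysis
#'
#' Simulates the dataset, then performs the complete analysis: peak calling
#' on all ChIP tracks, stage-unique active enhancer sets per lineage,
#' chromatin-state trajectories and their k-means archetypes, expression
#' normalisation with temporal clustering and PCA, coupling of stage-unique
#' enhancers to stage-specific expression, motif enrichment per stage and
#' lineage with TF nomination, the three TF-knockdown analyses, and the
#' two-TF co-regulation overlap.  Every result is compared against the
#' simulation truth and summarised in a deterministic report.
#'
#' @param config configuration list; missing keys take [default_config()]
#'   values.  Invalid configurations abort with the violations.
#' @param out_dir optional directory for TSV/BED artifacts and
#'   `report.json`; created if needed.
#' @return (invisibly) list with all intermediate objects and `report`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  viol <- validate_config(config)
  if (length(viol)) {
    stop("invalid config: ", paste(viol, collapse = "; "))
  }
  config <- utils::modifyList(default_config(), config)
  cfg <- sim_config(seed = as.integer(config$seed),
                    n_chroms = as.integer(config$n_chroms),
                    chrom_len = config$chrom_len,
                    n_genes = as.integer(config$n_genes),
                    n_per_class = as.integer(config$n_per_class),
                    cobound_targets = as.integer(config$cobound_targets),
                    bin_size = as.integer(config$bin_size),
                    chip_depth = config$chip_depth,
                    motif_pvalue = config$motif_pvalue)
  ds <- simulate_dataset(cfg)
  stages <- list(astro = config$stages_astro, neuro = config$stages_neuro)
  needed <- paste(rep(c("H3K4me1", "H3K27ac"), each = 6),
                  unlist(stages), sep = "/")
  if (!all(needed %in% names(ds$chip))) {
    stop("configured stages not present in the simulated tracks")
  }
  ann <- ds$annotation

  ## -- peaks and stage-unique active enhancer sets ------------------------
  peaks <- lapply(ds$chip, call_peaks, fdr = config$peak_fdr,
                  min_log2fc = config$peak_min_log2fc)
  unique_sets <- list()
  for (lin in names(stages)) {
    sets <- stats::setNames(
      lapply(stages[[lin]], function(s) peaks[[paste0("H3K27ac/", s)]]),
      stages[[lin]])
    us <- stage_unique_sets(sets, min_bp = config$min_overlap_bp)
    unique_sets[[lin]] <- lapply(us, `[[`, "unique")
  }

  ## -- consensus regions, states, trajectories ----------------------------
  regions <- GenomicRanges::reduce(
    suppressWarnings(do.call(c, unname(peaks))), ignore.strand = TRUE)
  sig_all <- enrichment_matrix(regions, ds$chip, ds$input)
  marked <- list()
  for (mark in c("H3K4me1", "H3K27ac")) {
    marked[[mark]] <- lapply(stages, function(ss) {
      sub <- sig_all[, paste(mark, ss, sep = "/"), drop = FALSE]
      attr(sub, "kind") <- "log2_enrichment"  # subsetting drops it
      m <- marked_status(sub, threshold = config$marked_threshold)
      colnames(m) <- ss
      m
    })
  }
  trajectories <- build_trajectories(marked$H3K4me1, marked$H3K27ac)
  clusters <- cluster_trajectories(sig_all, k = config$n_region_clusters,
                                   seed = config$seed,
                                   silhouette = length(regions) <= 5000)
  truth_gr <- GenomicRanges::GRanges(
    ds$truth$chrom, IRanges::IRanges(ds$truth$start, ds$truth$end))
  region_class <- match_truth_class(regions, truth_gr, ds$truth$class)
  annotation_category <- annotate_region(regions, ann)

  ## -- expression ----------------------------------------------------------
  expr <- ds$expression
  norm <- normalize_log2(expr$counts)
  conds <- unique(expr$design$stage)
  stage_expr <- vapply(conds, function(s) {
    rowMeans(norm[, expr$design$sample[expr$design$stage == s],
                  drop = FALSE])
  }, numeric(nrow(norm)))
  de <- de_test(expr$counts,
                expr$design$sample[expr$design$stage == stages$astro[1]],
                expr$design$sample[expr$design$stage == stages$astro[3]],
                fdr_cut = config$de_fdr)
  temporal <- temporal_clusters(stage_expr[, c("ESC", stages$astro)],
                                k = config$n_temporal_clusters,
                                seed = config$seed)
  pca <- pca_samples(expr$counts)

  ## -- enhancer-expression coupling ----------------------------------------
  coupling <- expression_coupling(unique_sets$astro, ann, stage_expr,
                                  max_tss_dist = config$max_tss_dist)

  ## -- motif enrichment and TF nomination ----------------------------------
  pool <- with_substream(config$seed, "background_pool", {
    # enhancer-free stretch of each gene unit: 13-19 kb from the unit start
    units <- data.frame(chrom = ds$gene_table$chrom,
                        unit_start = ds$gene_table$start - 2000L)
    s <- units$unit_start + 13000L +
      round(stats::runif(nrow(units), 0, 5400))
    GenomicRanges::GRanges(units$chrom,
                           IRanges::IRanges(s, width = cfg$enhancer_width))
  })
  enrich <- list()
  nominations <- list()
  for (lin in names(stages)) {
    enrich[[lin]] <- lapply(stats::setNames(stages[[lin]], stages[[lin]]),
                            function(s) {
      targets <- unique_sets[[lin]][[s]]
      bg <- gc_matched_background(targets, pool, ds$genome,
                                  ratio = config$background_ratio,
                                  bins = config$gc_bins,
                                  seed = config$seed)
      motif_enrichment(targets, bg, ds$genome, ds$pwms,
                       thresholds = ds$thresholds)
    })
  }
  for (j in 1:3) {
    sa <- stages$astro[j]
    sn <- stages$neuro[j]
    nominations[[sa]] <- nominate_tfs(enrich$astro[[sa]],
                                      enrich$neuro[[sn]],
                                      ds$motif2tf, stage_expr, sa)
  }

  ## -- knockdowns -----------------------------------------------------------
  kd_results <- list()
  for (tf in names(ds$knockdowns)) {
    kd <- ds$knockdowns[[tf]]
    tfr <- ds$tf_table[ds$tf_table$tf_gene == tf, ]
    su <- unique_sets$astro[[kd$stage]]
    sites <- target_sites(su, ds$pwms[[tfr$motif_id]], ds$genome,
                          ds$thresholds[[tfr$motif_id]])
    chrom_eff <- kd_chromatin_effect(kd$control_track, kd$kd_track,
                                     ds$input, sites)
    ctrl_cols <- kd$design$sample[kd$design$condition == "control"]
    kd_cols <- setdiff(kd$design$sample, ctrl_cols)
    deg <- kd_deregulated_genes(kd$counts, ctrl_cols, kd_cols,
                                fdr_cut = config$kd_fdr)
    inp <- quantify(ds$input, su)
    delta_all <- log2_enrichment(quantify(kd$kd_track, su), inp,
                                 kd$kd_track$library_size,
                                 ds$input$library_size) -
      log2_enrichment(quantify(kd$control_track, su), inp,
                      kd$control_track$library_size,
                      ds$input$library_size)
    link <- link_deregulated_to_sites(deg$table, su, delta_all, ann,
                                      max_tss_dist = config$max_tss_dist,
                                      fdr_cut = config$kd_fdr)
    kd_results[[tf]] <- list(
      tf = tf, stage = kd$stage, remodeling = kd$remodeling,
      sites = sites, chromatin = chrom_eff, deregulated = deg,
      link = link, target_genes = kd$target_genes)
  }
  both_motif_genes <- ds$truth$linked_gene[
    vapply(strsplit(ds$truth$motifs, ","), function(m)
      all(c("M_eA1", "M_eA2") %in% m), logical(1))]
  both_motif_genes <- both_motif_genes[!is.na(both_motif_genes)]
  rem <- ds$tf_table$tf_gene[ds$tf_table$remodeling]
  coreg_called <- coregulation_overlap(
    kd_results[[rem[1]]]$deregulated$down,
    kd_results[[rem[2]]]$deregulated$down,
    rownames(expr$counts), both_motif_genes)
  coreg_truth <- coregulation_overlap(
    ds$knockdowns[[rem[1]]]$target_genes,
    ds$knockdowns[[rem[2]]]$target_genes,
    rownames(expr$counts), both_motif_genes)

  ## -- truth recovery -------------------------------------------------------
  unique_recovery <- list()
  for (j in seq_along(stages$astro)) {
    s <- stages$astro[j]
    cls <- c("aNPC_unique", "eA_unique", "lA_unique")[j]
    unique_recovery[[s]] <- overlap_precision_recall(
      unique_sets$astro[[s]], truth_gr[ds$truth$class == cls])
  }
  act_truth <- data.frame(
    class = c("eA_unique", "lA_unique", "eN_unique", "lN_unique"),
    col = c("activation_stage_astro", "activation_stage_astro",
            "activation_stage_neuro", "activation_stage_neuro"),
    stage = c("eA", "lA", "eN", "lN"), stringsAsFactors = FALSE)
  correct <- 0L
  total <- 0L
  for (r in seq_len(nrow(act_truth))) {
    idx <- which(ds$truth$class == act_truth$class[r])
    hits <- GenomicRanges::findOverlaps(truth_gr[idx], regions,
                                        ignore.strand = TRUE)
    lab <- rep(NA_character_, length(idx))
    lab[S4Vectors::queryHits(hits)] <-
      trajectories[[act_truth$col[r]]][S4Vectors::subjectHits(hits)]
    correct <- correct + sum(lab == act_truth$stage[r], na.rm = TRUE)
    total <- total + length(idx)
  }
  traj_accuracy <- correct / total
  matched <- !is.na(region_class)
  ari <- adjusted_rand_index(clusters$assignments[matched],
                             region_class[matched])

  report <- list(
    seed = config$seed,
    n_regions = length(regions),
    n_peaks = vapply(peaks, length, integer(1)),
    unique_set_sizes = lapply(unique_sets, function(l)
      vapply(l, length, integer(1))),
    unique_recovery = unique_recovery,
    trajectory_label_accuracy = traj_accuracy,
    cluster_ari = ari,
    cluster_silhouette = clusters$silhouette,
    n_de_progenitor_vs_late = sum(de$de),
    coupling = lapply(coupling, function(x)
      list(n_genes = length(x$genes), median_own = x$median_own,
           median_other = x$median_other, p = x$p)),
    motif_nominations = lapply(nominations, function(x)
      list(candidates = x$candidates$tf_gene, common = x$common)),
    knockdowns = lapply(kd_results, function(x)
      list(tf = x$tf, stage = x$stage, remodeling = x$remodeling,
           n_sites = length(x$sites),
           median_delta = x$chromatin$median_delta,
           chromatin_p = x$chromatin$p,
           n_down = length(x$deregulated$down),
           n_up = length(x$deregulated$up),
           link_p = x$link$p)),
    coregulation = list(
      called_overlap = coreg_called$overlap, called_p = coreg_called$p,
      called_co_bound = coreg_called$co_bound,
      truth_overlap = coreg_truth$overlap, truth_p = coreg_truth$p,
      truth_co_bound = coreg_truth$co_bound)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (cond in names(peaks)) {
      write_bed(peaks[[cond]],
                file.path(out_dir, paste0("peaks_", gsub("/", "_", cond),
                                          ".bed")))
    }
    traj_out <- cbind(trajectories,
                      cluster = unname(clusters$assignments),
                      truth_class = region_class,
                      category = annotation_category)
    utils::write.table(traj_out, file.path(out_dir, "trajectories.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(de, file.path(out_dir, "de_progenitor_vs_late.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(gene = names(temporal$assignments),
                 cluster = unname(temporal$assignments)),
      file.path(out_dir, "temporal_clusters.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    for (lin in names(enrich)) {
      for (s in names(enrich[[lin]])) {
        utils::write.table(
          enrich[[lin]][[s]],
          file.path(out_dir, paste0("motif_enrichment_", lin, "_", s,
                                    ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(
    config = config, sim_config = cfg, data = ds, peaks = peaks,
    unique_sets = unique_sets, regions = regions, signal = sig_all,
    trajectories = trajectories, clusters = clusters,
    region_class = region_class, stage_expr = stage_expr, de = de,
    temporal = temporal, pca = pca, coupling = coupling,
    enrichment = enrich, nominations = nominations,
    knockdowns = kd_results, coregulation = coreg_called,
    coregulation_truth = coreg_truth, report = report
  ))
}
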