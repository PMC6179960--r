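#' Stage-unique peaks carrying a TF's motif
#'
#' @param unique_peaks `GRanges` of stage-unique H3K27ac peaks.
#' @param pwm the TF's `PWM`.
#' @param genome named `DNAStringSet`.
#' @param threshold motif score threshold.
#' @return `GRanges` subset of `unique_peaks` with metadata columns
#'   `n_hits` and `best_score`.
#' @export
target_sites <- function(unique_peaks, pwm, genome, threshold) {
  seqs <- region_sequences(genome, unique_peaks)
  hits <- lapply(seqs, function(s) scan_sequence(pwm, s, threshold))
  n <- vapply(hits, nrow, integer(1))
  out <- unique_peaks[n > 0]
  mcols(out)$n_hits <- n[n > 0]
  mcols(out)$best_score <- vapply(hits[n > 0],
                                  function(h) max(h$score), numeric(1))
  out
}

#' Knockdown effect on active chromatin at target sites
#'
#' Per site, the change in H3K27ac log2 enrichment over the genomic input
#' between knockdown and control (`delta = kd - control`), tested for a
#' shift below zero with a one-sided paired Wilcoxon signed-rank test.
#' Also returns the mean profile around the site midpoints under both
#' conditions for profile plots.
#'
#' @param control_track,kd_track H3K27ac `BinnedTrack`s, identically binned.
#' @param input_track genomic input `BinnedTrack`.
#' @param sites `GRanges` of motif-bearing target sites (>= 10).
#' @param pseudocount pseudocount for enrichment.
#' @param window,n_bins profile geometry (see [profile_matrix()]).
#' @return list: `delta` (per site), `median_delta`, `p`, `degenerate`
#'   (all deltas zero), `profile_control`, `profile_kd` (column means),
#'   `test` (description of the test orientation).
#' @export
kd_chromatin_effect <- function(control_track, kd_track, input_track, sites,
                                pseudocount = 1, window = 2000L,
                                n_bins = 41L) {
  if (length(sites) < 10) stop("need >= 10 target sites")
  if (control_track$bin_size != kd_track$bin_size) {
    stop("control and knockdown tracks binned differently")
  }
  keep <- as.character(seqnames(sites)) %in% names(control_track$counts)
  if (!all(keep)) {
    warning(sum(!keep), " site(s) on chromosomes missing from the tracks ",
            "dropped")
    sites <- sites[keep]
  }
  inp <- quantify(input_track, sites)
  enr_c <- log2_enrichment(quantify(control_track, sites), inp,
                           control_track$library_size,
                           input_track$library_size, pseudocount)
  enr_k <- log2_enrichment(quantify(kd_track, sites), inp,
                           kd_track$library_size,
                           input_track$library_size, pseudocount)
  delta <- enr_k - enr_c
  degenerate <- all(delta == 0)
  p <- if (degenerate) 1 else {
    suppressWarnings(stats::wilcox.test(delta, mu = 0,
                                        alternative = "less")$p.value)
  }
  pc <- colMeans(profile_matrix(control_track, sites, window, n_bins,
                                input = input_track,
                                pseudocount = pseudocount))
  pk <- colMeans(profile_matrix(kd_track, sites, window, n_bins,
                                input = input_track,
                                pseudocount = pseudocount))
  list(delta = delta, median_delta = stats::median(delta), p = p,
       degenerate = degenerate, profile_control = pc, profile_kd = pk,
       test = "one-sided paired Wilcoxon signed-rank, H1: delta < 0")
}

#' Deregulated genes after a TF knockdown
#'
#' A negative-binomial contrast of knockdown versus control samples (see
#' [de_test()]); downregulated genes have `log2fc < 0` at `fdr < fdr_cut`,
#' upregulated genes `log2fc > 0`.
#'
#' @param counts gene x sample count matrix containing both conditions.
#' @param control_cols,kd_cols column names/indices (>= 2 each).
#' @param fdr_cut FDR cutoff (default 0.1).
#' @return list: `up`, `down` (gene id vectors), `table` (full
#'   [de_test()] output; `log2fc` is knockdown over control).
#' @export
kd_deregulated_genes <- function(counts, control_cols, kd_cols,
                                 fdr_cut = 0.1) {
  tab <- de_test(counts, control_cols, kd_cols, fdr_cut = fdr_cut)
  list(up = tab$gene[tab$de & tab$log2fc > 0],
       down = tab$gene[tab$de & tab$log2fc < 0],
       table = tab)
}

#' Link deregulated genes to regulatory sites and compare chromatin change
#'
#' Assigns each site to its nearest gene, classifies sites by the gene's
#' knockdown response (down / up / unchanged, where unchanged means
#' `fdr >= unchanged_fdr` and `|log2fc| < unchanged_lfc`), and tests
#' whether sites linked to downregulated genes lose more H3K27ac than
#' sites linked to unchanged genes (one-sided rank-sum).  Classes with
#' fewer than 5 sites skip the test.
#'
#' @param de_table output table of [de_test()] for the knockdown contrast.
#' @param sites `GRanges` of regulatory sites.
#' @param delta per-site knockdown chromatin effect, parallel to `sites`.
#' @param ann a `GenomeAnnotation`.
#' @param max_tss_dist passed to [assign_nearest_gene()].
#' @param fdr_cut FDR defining up/down (default 0.1).
#' @param unchanged_fdr,unchanged_lfc bounds defining the unchanged class.
#' @return list: `delta_by_class` (list of numeric vectors), `p`
#'   (down vs unchanged, `NA` when skipped), `skipped`, `classes`
#'   (per-site class).
#' @export
link_deregulated_to_sites <- function(de_table, sites, delta, ann,
                                      max_tss_dist = 50000L, fdr_cut = 0.1,
                                      unchanged_fdr = 0.5,
                                      unchanged_lfc = 0.25) {
  stopifnot(length(delta) == length(sites))
  gene <- assign_nearest_gene(sites, ann, max_tss_dist)
  idx <- match(gene, de_table$gene)
  cls <- rep(NA_character_, length(sites))
  hit <- !is.na(idx)
  fdr <- de_table$fdr[idx[hit]]
  lfc <- de_table$log2fc[idx[hit]]
  cl <- rep(NA_character_, sum(hit))
  cl[fdr < fdr_cut & lfc < 0] <- "down"
  cl[fdr < fdr_cut & lfc > 0] <- "up"
  cl[fdr >= unchanged_fdr & abs(lfc) < unchanged_lfc] <- "unchanged"
  cls[hit] <- cl
  by_class <- split(delta, cls)
  skipped <- length(by_class$down %||% numeric(0)) < 5 ||
    length(by_class$unchanged %||% numeric(0)) < 5
  p <- if (skipped) NA_real_ else {
    suppressWarnings(stats::wilcox.test(by_class$down, by_class$unchanged,
                                        alternative = "less")$p.value)
  }
  list(delta_by_class = by_class, p = p, skipped = skipped, classes = cls,
       test = "one-sided rank-sum, H1: delta(down) < delta(unchanged)")
}

#' Two-TF co-regulation overlap with hypergeometric significance
#'
#' Overlap of the two downregulated gene sets, a one-sided hypergeometric
#' p-value for an overlap at least that large given the detected-gene
#' universe, and the number of overlapping genes whose regulatory sites
#' carry both TFs' motifs.
#'
#' @param down_a,down_b character vectors of downregulated genes.
#' @param universe either the universe size (integer) or the character
#'   vector of detected genes.
#' @param both_motif_genes genes whose sites carry both motifs.
#' @return list: `overlap_genes`, `overlap`, `p`, `co_bound`.
#' @export
coregulation_overlap <- function(down_a, down_b, universe,
                                 both_motif_genes = character(0)) {
  n_universe <- if (is.numeric(universe)) universe else length(universe)
  if (!is.numeric(universe)) {
    down_a <- intersect(down_a, universe)
    down_b <- intersect(down_b, universe)
  }
  if (n_universe < max(length(down_a), length(down_b))) {
    stop("universe smaller than a gene set")
  }
  ov <- intersect(down_a, down_b)
  p <- stats::phyper(length(ov) - 1, length(down_a),
                     n_universe - length(down_a), length(down_b),
                     lower.tail = FALSE)
  list(overlap_genes = ov, overlap = length(ov), p = p,
       co_bound = length(intersect(ov, both_motif_genes)))
}
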