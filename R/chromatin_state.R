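#' Four-way chromatin state from H3K4me1 / H3K27ac marking
#'
#' H3K4me1 marks primed or active enhancers in the absence or presence of
#' H3K27ac respectively; H3K27ac without H3K4me1 is kept as a distinct
#' `acetyl_only` state so the 2x2 logic stays lossless.
#'
#' @param k4me1_marked,k27ac_marked logical vectors (recycled).
#' @return factor with levels none, primed, active, acetyl_only.
#' @export
assign_state <- function(k4me1_marked, k27ac_marked) {
  out <- ifelse(k4me1_marked & k27ac_marked, "active",
                ifelse(k4me1_marked, "primed",
                       ifelse(k27ac_marked, "acetyl_only", "none")))
  factor(out, levels = c("none", "primed", "active", "acetyl_only"))
}

#' Per-region chromatin-state trajectories across stages and lineages
#'
#' Combines marked/unmarked tables for the two histone marks into one state
#' per region, stage and lineage, and labels each region
#' "primed-then-activated at stage s" when it is primed at the stage
#' preceding s and active at s (the earliest such s is reported).
#'
#' @param k4me1,k27ac named lists with elements `astro` and `neuro`, each a
#'   logical regions x stages matrix (identical row order across all four).
#' @return data.frame with one row per region: the state at every
#'   stage/lineage plus `activation_stage_astro` / `activation_stage_neuro`
#'   (stage name or `NA`).
#' @export
build_trajectories <- function(k4me1, k27ac) {
  for (lin in c("astro", "neuro")) {
    if (!identical(dim(k4me1[[lin]]), dim(k27ac[[lin]]))) {
      stop("mismatched region/stage tables for lineage ", lin)
    }
    if (!identical(rownames(k4me1[[lin]]), rownames(k27ac[[lin]]))) {
      stop("mismatched region indices for lineage ", lin)
    }
  }
  if (!identical(rownames(k4me1$astro), rownames(k4me1$neuro))) {
    stop("mismatched region indices between lineages")
  }
  n <- nrow(k4me1$astro)
  out <- data.frame(region = rownames(k4me1$astro) %||% seq_len(n),
                    stringsAsFactors = FALSE)
  for (lin in c("astro", "neuro")) {
    stages <- colnames(k4me1[[lin]])
    st <- matrix("", n, length(stages))
    for (j in seq_along(stages)) {
      st[, j] <- as.character(assign_state(k4me1[[lin]][, j],
                                           k27ac[[lin]][, j]))
    }
    colnames(st) <- paste(lin, stages, sep = "_")
    out <- cbind(out, as.data.frame(st, stringsAsFactors = FALSE))
    act <- rep(NA_character_, n)
    for (j in rev(seq_along(stages))[-length(stages)]) {
      hit <- st[, j - 1] == "primed" & st[, j] == "active"
      act[hit] <- stages[j]  # reverse loop: earliest stage wins
    }
    out[[paste0("activation_stage_", lin)]] <- act
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' K-means clustering of chromatin trajectories
#'
#' Rows (regions) are z-scored and partitioned by k-means with Euclidean
#' distance and multiple restarts; deterministic for a given seed.  Rows
#' with (near-)zero variance are dropped with a warning before clustering.
#'
#' @param sig numeric matrix, regions x (stage, mark, lineage) enrichment.
#' @param k number of clusters (>= 2).
#' @param seed RNG seed.
#' @param restarts number of k-means restarts (default 25).
#' @param silhouette compute the mean silhouette width (skipped above 5000
#'   rows).
#' @return list with `assignments` (named integer vector), `centroids`,
#'   `k`, `seed`, `tot_withinss` and `silhouette`.
#' @export
cluster_trajectories <- function(sig, k = 7L, seed = 1L, restarts = 25L,
                                 silhouette = TRUE) {
  if (k < 2) stop("k must be >= 2")
  z <- zscore_rows(sig)
  n_distinct <- nrow(unique(z))
  if (k > n_distinct) {
    stop("k (", k, ") exceeds the number of distinct rows (", n_distinct, ")")
  }
  km <- with_substream(seed, "cluster_trajectories",
                       stats::kmeans(z, centers = k, nstart = restarts,
                                     iter.max = 100))
  sil <- NA_real_
  if (silhouette && nrow(z) <= 5000 && k >= 2) {
    sil <- mean_silhouette(z, km$cluster)
  }
  list(assignments = stats::setNames(km$cluster, rownames(z)),
       centroids = km$centers, k = k, seed = seed,
       tot_withinss = km$tot.withinss, silhouette = sil)
}

# Mean silhouette width over all points (Euclidean distance).
mean_silhouette <- function(x, cluster) {
  d <- as.matrix(stats::dist(x))
  ids <- sort(unique(cluster))
  if (length(ids) < 2) return(NA_real_)
  s <- numeric(length(cluster))
  for (i in seq_along(cluster)) {
    own <- cluster == cluster[i]
    a <- if (sum(own) > 1) sum(d[i, own]) / (sum(own) - 1) else 0
    b <- min(vapply(ids[ids != cluster[i]],
                    function(cl) mean(d[i, cluster == cl]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Couple stage-unique active elements to stage-specific expression
#'
#' Assigns genes to each stage's unique active peaks with
#' [assign_nearest_gene()], keeps only genes assigned to exactly one stage
#' (the non-overlapping Venn sets), and tests per stage whether those genes
#' are expressed higher at their own stage than at the other stages
#' (one-sided Mann-Whitney rank-sum on log2-normalised expression).
#'
#' @param unique_active named list of `GRanges`, one per stage.
#' @param ann a `GenomeAnnotation`.
#' @param expr numeric gene x stage matrix of log2-normalised expression;
#'   column names must include the stages in `unique_active`.
#' @param max_tss_dist passed to [assign_nearest_gene()].
#' @return list per stage: `genes`, `median_own`, `median_other`, `p`
#'   (`NA` with `skipped = TRUE` when the gene set is empty).
#' @export
expression_coupling <- function(unique_active, ann, expr,
                                max_tss_dist = 50000L) {
  stages <- names(unique_active)
  stopifnot(all(stages %in% colnames(expr)))
  assigned <- lapply(unique_active, function(gr) {
    g <- assign_nearest_gene(gr, ann, max_tss_dist)
    unique(g[!is.na(g)])
  })
  tabs <- table(unlist(assigned))
  multi <- names(tabs)[tabs > 1]
  assigned <- lapply(assigned, function(g) setdiff(g, multi))

  out <- list()
  for (s in stages) {
    genes <- intersect(assigned[[s]], rownames(expr))
    if (length(genes) == 0) {
      out[[s]] <- list(genes = character(0), median_own = NA_real_,
                       median_other = NA_real_, p = NA_real_, skipped = TRUE)
      next
    }
    own <- expr[genes, s]
    other <- as.vector(expr[genes, setdiff(stages, s), drop = FALSE])
    p <- if (stats::sd(c(own, other)) == 0) 1 else {
      suppressWarnings(stats::wilcox.test(own, other,
                                          alternative = "greater")$p.value)
    }
    out[[s]] <- list(genes = genes, median_own = stats::median(own),
                     median_other = stats::median(other), p = p,
                     skipped = FALSE)
  }
  out
}
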