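# Naive reference implementations (oracles) and shared fixtures for the
# test suite.  Oracles trade efficiency for obvious correctness.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

random_regions <- function(seed, n, chroms = c("chrA", "chrB"),
                           max_pos = 10000L, max_width = 200L) {
  withr::with_seed(seed, {
    GenomicRanges::GRanges(
      sample(chroms, n, replace = TRUE),
      IRanges::IRanges(sample.int(max_pos, n, replace = TRUE),
                       width = sample.int(max_width, n, replace = TRUE)))
  })
}

# O(n^2) interval-overlap oracle on 1-based closed coordinates.
oracle_overlaps <- function(a, b, min_bp = 1L) {
  ca <- as.character(seqnames(a)); cb <- as.character(seqnames(b))
  sa <- start(a); ea <- end(a); sb <- start(b); eb <- end(b)
  qs <- ss <- ob <- integer(0)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      if (ca[i] != cb[j]) next
      ov <- min(ea[i], eb[j]) - max(sa[i], sb[j]) + 1L
      if (ov >= min_bp) {
        qs <- c(qs, i); ss <- c(ss, j); ob <- c(ob, ov)
      }
    }
  }
  out <- data.frame(query = qs, subject = ss, overlap_bp = ob)
  out[order(out$query, out$subject), , drop = FALSE]
}

random_dna <- function(seed, n) {
  withr::with_seed(seed,
                   paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                         collapse = ""))
}

revcomp_str <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(map[strsplit(s, "")[[1]]])), collapse = "")
}

# Log2-odds score of a PWM on one exact-width string (NA on non-ACGT).
score_string <- function(p, s) {
  codes <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  if (anyNA(codes)) return(NA_real_)
  sum(p$log_odds[cbind(seq_len(p$width), codes)])
}

# Naive both-strand scan oracle: per start, max of forward score and the
# score of the reverse complement of the window.
oracle_scan <- function(p, seqstr, threshold) {
  n <- nchar(seqstr) - p$width + 1L
  if (n < 1) {
    return(data.frame(pos = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  rows <- list()
  for (i in seq_len(n)) {
    win <- substr(seqstr, i, i + p$width - 1L)
    f <- score_string(p, win)
    r <- score_string(p, revcomp_str(win))
    if (is.na(f) || is.na(r)) next
    best <- max(f, r)
    if (best >= threshold) {
      rows[[length(rows) + 1L]] <-
        data.frame(pos = i, strand = if (f >= r) "+" else "-", score = best,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(pos = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  do.call(rbind, rows)
}

# Exact null tail P(score >= t) for a PWM by enumerating all 4^w sequences
# under the background model, with scores discretised exactly as the
# calibration does.
oracle_tail <- function(p, t, bin = 0.005) {
  sc <- round(p$log_odds / bin)
  combos <- expand.grid(rep(list(1:4), p$width))
  total <- 0
  for (r in seq_len(nrow(combos))) {
    codes <- as.integer(combos[r, ])
    s <- sum(sc[cbind(seq_len(p$width), codes)]) * bin
    if (s >= t) total <- total + prod(p$background[codes])
  }
  total
}

# Direct hypergeometric upper tail by summation of dhyper.
oracle_phyper_tail <- function(q, white, black, drawn) {
  k <- q:min(white, drawn)
  sum(stats::dhyper(k, white, black, drawn))
}

# A small synthetic dataset shared by module tests (cached per session).
.test_cache <- new.env(parent = emptyenv())
small_dataset <- function(seed = 11L) {
  key <- paste0("ds_", seed)
  if (is.null(.test_cache[[key]])) {
    cfg <- sim_config(seed = seed, n_chroms = 2L, chrom_len = 1.7e6,
                      n_genes = 160L, n_per_class = 20L,
                      cobound_targets = 8L, chip_depth = 4e5)
    .test_cache[[key]] <- simulate_dataset(cfg)
  }
  .test_cache[[key]]
}

# The default-configuration pipeline run shared by the acceptance tests
# (cached per session; ~2 min on first use).  Wall time is recorded.
full_pipeline_run <- function() {
  if (is.null(.test_cache$full_run)) {
    t0 <- proc.time()[["elapsed"]]
    .test_cache$full_run <-
      suppressWarnings(run_pipeline(default_config()))
    .test_cache$full_elapsed <- proc.time()[["elapsed"]] - t0
  }
  .test_cache$full_run
}
full_pipeline_elapsed <- function() {
  full_pipeline_run()
  .test_cache$full_elapsed
}

# Simple gene table for annotation tests: two genes on chrA, one on chrB.
toy_gene_table <- function() {
  data.frame(
    gene_id = c("gA1", "gA2", "gB1"),
    chrom = c("chrA", "chrA", "chrB"),
    strand = c("+", "-", "+"),
    start = c(2001L, 12001L, 5001L),
    end = c(4000L, 14000L, 7000L),
    exon_starts = c("2001,3501", "12001,13501", "5001,6501"),
    exon_ends = c("2500,4000", "12500,14000", "5500,7000"),
    stringsAsFactors = FALSE
  )
}
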