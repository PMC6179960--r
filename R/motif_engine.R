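#' Construct a position weight matrix
#'
#' Rows are positions, columns the bases A, C, G, T; each row must sum to 1
#' (within 1e-6).  Probabilities are floored at 1e-3 before log-odds are
#' taken against the background, so scores stay finite.
#'
#' @param mat numeric width x 4 matrix of base probabilities.
#' @param motif_id motif identifier.
#' @param tf_name transcription-factor gene symbol (defaults to `motif_id`).
#' @param background base composition of the null model (default uniform).
#' @return object of class `PWM` with the log2-odds matrix precomputed.
#' @export
pwm <- function(mat, motif_id, tf_name = motif_id,
                background = rep(0.25, 4)) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4) stop("PWM must have 4 columns (A, C, G, T)")
  if (nrow(mat) < 1) stop("PWM must have width >= 1")
  if (any(abs(rowSums(mat) - 1) > 1e-6)) stop("PWM rows must sum to 1")
  if (any(abs(sum(background) - 1) > 1e-6)) stop("background must sum to 1")
  colnames(mat) <- c("A", "C", "G", "T")
  lo <- log2(pmax(mat, 1e-3) / rep(background, each = nrow(mat)))
  structure(list(motif_id = motif_id, tf_name = tf_name, matrix = mat,
                 background = background, log_odds = lo,
                 width = nrow(mat)),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat("PWM", x$motif_id, "(", x$tf_name, ") width", x$width, "\n")
  invisible(x)
}

#' Read / write a PWM library in a JASPAR-like text format
#'
#' Each record is a header line `>motif_id tf_name` followed by four lines
#' `A|C|G|T p1 p2 ... pw` of base probabilities.
#'
#' @param path file path.
#' @return named list of `PWM` objects (for the reader).
#' @export
read_pwms <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  out <- list()
  for (s in seq_along(starts)) {
    hdr <- strsplit(sub("^>", "", lines[starts[s]]), "\\s+")[[1]]
    block <- strsplit(trimws(lines[(starts[s] + 1):(starts[s] + 4)]), "\\s+")
    rows <- lapply(block, function(f) as.numeric(f[-1]))
    names(rows) <- vapply(block, `[[`, "", 1L)
    mat <- t(do.call(rbind, rows[c("A", "C", "G", "T")]))
    p <- pwm(mat, hdr[1], if (length(hdr) > 1) hdr[2] else hdr[1])
    out[[p$motif_id]] <- p
  }
  out
}

#' @rdname read_pwms
#' @param pwms named list of `PWM` objects to write.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$motif_id, " ", p$tf_name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(paste(b, paste(formatC(p$matrix[, b], digits = 6,
                                        format = "f"), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Exact score threshold for a PWM at a null p-value
#'
#' Computes the exact null distribution of the log2-odds score under the
#' PWM's background model by position-wise dynamic programming over scores
#' discretised to `bin`-wide cells, and returns the smallest discrete score
#' whose null tail probability is at most `pvalue`.  If `pvalue` is below
#' the minimal attainable tail, the maximal score is returned with a
#' warning.
#'
#' @param pwm a `PWM`.
#' @param pvalue target null tail probability (default 1e-4).
#' @param bin score discretisation width (default 0.005, must be <= 0.01).
#' @return numeric threshold; attribute `tail_prob` holds the attained tail.
#' @export
calibrate_threshold <- function(pwm, pvalue = 1e-4, bin = 0.005) {
  if (pvalue <= 0 || pvalue >= 1) stop("pvalue must be in (0, 1)")
  if (bin > 0.01) stop("bin width must be <= 0.01")
  sc <- round(pwm$log_odds / bin)  # integer scores per position/base
  lo_min <- sum(apply(sc, 1, min))
  lo_max <- sum(apply(sc, 1, max))
  # bounds wide enough for every intermediate partial sum
  neg_sum <- sum(pmin(apply(sc, 1, min), 0))
  pos_sum <- sum(pmax(apply(sc, 1, max), 0))
  offset <- 1L - as.integer(neg_sum)  # index of integer score s is s + offset
  size <- as.integer(pos_sum) + offset
  cur <- numeric(size)
  cur[offset] <- 1  # score 0 before any position
  # running attainable range keeps the convolution tight
  run_min <- 0L
  run_max <- 0L
  for (i in seq_len(pwm$width)) {
    nxt <- numeric(size)
    for (b in 1:4) {
      s <- sc[i, b]
      pr <- pwm$background[b]
      if (pr == 0) next
      idx <- (run_min:run_max) + offset
      shifted <- idx + s
      valid <- shifted >= 1 & shifted <= size
      nxt[shifted[valid]] <- nxt[shifted[valid]] + cur[idx[valid]] * pr
    }
    cur <- nxt
    run_min <- run_min + min(sc[i, pwm$background > 0])
    run_max <- run_max + max(sc[i, pwm$background > 0])
  }
  tail <- rev(cumsum(rev(cur)))  # tail[i] = P(score_int >= i - offset)
  scores_int <- seq_len(size) - offset
  ok <- which(tail <= pvalue)
  if (!length(ok)) {
    warning("pvalue below minimal attainable tail; returning maximal score")
    thr_int <- lo_max
    attained <- tail[lo_max + offset]
  } else {
    thr_int <- scores_int[ok[1]]
    attained <- tail[ok[1]]
  }
  thr <- thr_int * bin
  attr(thr, "tail_prob") <- attained
  thr
}

# Map a DNA string to integer codes 1..4 (A,C,G,T); anything else is NA.
dna_codes <- function(seq) {
  v <- strsplit(toupper(as.character(seq)), "", fixed = TRUE)[[1]]
  match(v, c("A", "C", "G", "T"))
}

# Sliding log2-odds scores of a PWM along an integer-coded sequence.
# Windows containing non-ACGT characters score NA.
slide_scores <- function(lo, codes) {
  w <- nrow(lo)
  n <- length(codes) - w + 1
  if (n < 1) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(w)) {
    sc <- sc + lo[j, ][codes[j:(j + n - 1)]]
  }
  sc
}

#' Scan a sequence with a PWM on both strands
#'
#' At each start position the forward score and the reverse-complement
#' score are computed as plain per-window log2-odds sums; the position is a
#' hit when the larger of the two reaches `threshold`.  Windows containing
#' `N` are skipped.
#'
#' @param pwm a `PWM`.
#' @param sequence DNA string (character or `DNAString`).
#' @param threshold score threshold, typically from [calibrate_threshold()].
#' @return data.frame with `pos` (1-based start), `strand`, `score` for
#'   every hit; zero rows when the sequence is shorter than the motif.
#' @export
scan_sequence <- function(pwm, sequence, threshold) {
  codes <- dna_codes(sequence)
  fwd <- slide_scores(pwm$log_odds, codes)
  if (!length(fwd)) {
    return(data.frame(pos = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  # reverse-complement score at the same start coordinate
  lo_rc <- pwm$log_odds[rev(seq_len(pwm$width)), c(4, 3, 2, 1), drop = FALSE]
  rvs <- slide_scores(lo_rc, codes)
  best <- pmax(fwd, rvs)
  hit <- which(!is.na(best) & best >= threshold)
  data.frame(
    pos = hit,
    # as.character keeps the column typed when there are no hits
    strand = as.character(ifelse(fwd[hit] >= rvs[hit], "+", "-")),
    score = best[hit],
    stringsAsFactors = FALSE
  )
}

# Extract region sequences from a DNAStringSet genome.
region_sequences <- function(genome, regions) {
  chroms <- as.character(seqnames(regions))
  missing <- setdiff(unique(chroms), names(genome))
  if (length(missing)) {
    stop("chromosome(s) missing from genome: ",
         paste(missing, collapse = ", "))
  }
  vapply(seq_along(regions), function(i) {
    as.character(Biostrings::subseq(genome[[chroms[i]]],
                                    start = start(regions)[i],
                                    end = end(regions)[i]))
  }, character(1))
}

#' Region-level motif hits
#'
#' @param pwm a `PWM`.
#' @param regions `GRanges`.
#' @param genome named `DNAStringSet`.
#' @param threshold score threshold.
#' @return logical vector: does each region contain at least one hit?
#' @export
region_hits <- function(pwm, regions, genome, threshold) {
  seqs <- region_sequences(genome, regions)
  vapply(seqs, function(s) nrow(scan_sequence(pwm, s, threshold)) > 0,
         logical(1), USE.NAMES = FALSE)
}

#' GC content of regions
#' @inheritParams region_hits
#' @return numeric vector of GC fractions.
#' @export
gc_content <- function(regions, genome) {
  seqs <- Biostrings::DNAStringSet(region_sequences(genome, regions))
  as.numeric(Biostrings::letterFrequency(seqs, "GC", as.prob = TRUE))
}

#' GC-matched background region sampling
#'
#' Splits the target GC distribution into `bins` quantile bins and samples
#' pool regions without replacement so that each bin contributes
#' `ratio x` the target count in that bin (capped at availability, with a
#' warning).  Pool regions overlapping a target are excluded.  Seeded and
#' deterministic.
#'
#' @param targets,pool `GRanges`.
#' @param genome named `DNAStringSet`.
#' @param ratio background-to-target size ratio (default 2).
#' @param bins number of GC quantile bins (default 10).
#' @param seed RNG seed.
#' @return `GRanges` of sampled background regions.
#' @export
gc_matched_background <- function(targets, pool, genome, ratio = 2,
                                  bins = 10L, seed = 1L) {
  pool <- pool[!IRanges::overlapsAny(pool, targets,
                                           ignore.strand = TRUE)]
  gt <- gc_content(targets, genome)
  gp <- gc_content(pool, genome)
  breaks <- unique(stats::quantile(gt, probs = seq(0, 1, length.out = bins + 1)))
  breaks[1] <- -Inf
  breaks[length(breaks)] <- Inf
  bt <- cut(gt, breaks)
  bp <- cut(gp, breaks)
  picks <- integer(0)
  with_substream(seed, "gc_matched_background", {
    for (lev in levels(bt)) {
      need <- round(ratio * sum(bt == lev, na.rm = TRUE))
      if (need == 0) next
      avail <- which(bp == lev)
      if (length(avail) < need) {
        warning("GC bin ", lev, ": only ", length(avail), " of ", need,
                " background regions available")
        need <- length(avail)
      }
      if (need > 0) picks <- c(picks, sample(avail, need))
    }
  })
  pool[sort(picks)]
}

#' Motif enrichment of target regions over a background set
#'
#' Region-level hit counts in targets and background are compared with a
#' one-sided hypergeometric test (drawing the target set from the combined
#' urn of regions, successes = regions with a hit), or optionally a
#' one-sided binomial test against the background hit rate.  BH-FDR across
#' motifs; a motif is flagged enriched at `fdr < 0.05` with odds ratio > 1.
#'
#' @param targets,background `GRanges` region sets (targets non-empty).
#' @param genome named `DNAStringSet`.
#' @param pwms named list of `PWM`s.
#' @param thresholds named numeric vector of score thresholds per motif
#'   (calibrated at `pvalue` when omitted).
#' @param pvalue calibration p-value for [calibrate_threshold()].
#' @param method `"hypergeometric"` (default) or `"binomial"`.
#' @return data.frame: motif_id, tf_name, n_target, n_target_hit, n_bg,
#'   n_bg_hit, odds_ratio, p, fdr, enriched.
#' @export
motif_enrichment <- function(targets, background, genome, pwms,
                             thresholds = NULL, pvalue = 1e-4,
                             method = c("hypergeometric", "binomial")) {
  method <- match.arg(method)
  if (length(targets) == 0) stop("empty target set")
  if (is.null(thresholds)) {
    thresholds <- vapply(pwms, calibrate_threshold, numeric(1),
                         pvalue = pvalue)
  }
  tseq <- region_sequences(genome, targets)
  bseq <- region_sequences(genome, background)
  res <- lapply(names(pwms), function(id) {
    p <- pwms[[id]]
    thr <- thresholds[[id]]
    th <- sum(vapply(tseq, function(s) nrow(scan_sequence(p, s, thr)) > 0,
                     logical(1)))
    bh <- sum(vapply(bseq, function(s) nrow(scan_sequence(p, s, thr)) > 0,
                     logical(1)))
    nt <- length(targets)
    nb <- length(background)
    pv <- if (method == "hypergeometric") {
      stats::phyper(th - 1, th + bh, nt + nb - th - bh, nt,
                    lower.tail = FALSE)
    } else {
      rate <- max(bh / max(nb, 1), 1e-12)
      stats::pbinom(th - 1, nt, rate, lower.tail = FALSE)
    }
    or <- ((th + 0.5) / (nt - th + 0.5)) / ((bh + 0.5) / (nb - bh + 0.5))
    data.frame(motif_id = id, tf_name = p$tf_name, n_target = nt,
               n_target_hit = th, n_bg = nb, n_bg_hit = bh,
               odds_ratio = or, p = pv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$fdr < 0.05 & out$odds_ratio > 1
  out[order(out$p), ]
}

#' Partition two enriched-motif sets into unique and common motifs
#'
#' @param enriched_a,enriched_b character vectors of motif ids.
#' @return list with `unique_a`, `unique_b`, `common`.
#' @export
motif_set_comparison <- function(enriched_a, enriched_b) {
  list(unique_a = setdiff(enriched_a, enriched_b),
       unique_b = setdiff(enriched_b, enriched_a),
       common = intersect(enriched_a, enriched_b))
}

#' Nominate stage-specific transcription factors
#'
#' Candidates are motifs enriched at the astro stage's unique peaks but not
#' at the matched neuro stage's (motifs enriched in both are retained in a
#' separate `common` list), mapped to TF genes, filtered for expression of
#' the TF gene at the stage, and ranked by enrichment p-value.  Motifs
#' without a gene mapping are retained and flagged unmappable.
#'
#' @param astro_enrichment,neuro_enrichment results from
#'   [motif_enrichment()] for the matched astro/neuro stage pair.
#' @param motif2tf data.frame with columns `motif_id`, `gene`.
#' @param expr gene x stage matrix of log2-normalised expression.
#' @param stage astro stage name (column of `expr`).
#' @param min_expr minimum TF expression at the stage (default 1).
#' @return list with `candidates` (ranked data.frame) and `common`
#'   (character vector of motifs enriched in both lineages).
#' @export
nominate_tfs <- function(astro_enrichment, neuro_enrichment, motif2tf,
                         expr, stage, min_expr = 1) {
  ea <- astro_enrichment$motif_id[astro_enrichment$enriched]
  en <- neuro_enrichment$motif_id[neuro_enrichment$enriched]
  parts <- motif_set_comparison(ea, en)
  cand <- astro_enrichment[astro_enrichment$motif_id %in% parts$unique_a, ,
                           drop = FALSE]
  gene <- motif2tf$gene[match(cand$motif_id, motif2tf$motif_id)]
  mappable <- !is.na(gene)
  expressed <- rep(NA, nrow(cand))
  ex_val <- rep(NA_real_, nrow(cand))
  known <- mappable & gene %in% rownames(expr)
  ex_val[known] <- expr[gene[known], stage]
  expressed[known] <- ex_val[known] >= min_expr
  keep <- !mappable | (known & expressed)
  out <- data.frame(motif_id = cand$motif_id, tf_gene = gene,
                    p = cand$p, fdr = cand$fdr,
                    expression = ex_val,
                    unmappable = !mappable,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out <- out[order(out$p), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  list(candidates = out, common = parts$common)
}
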