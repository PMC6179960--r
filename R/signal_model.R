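#' Construct a binned read-count track
#'
#' A `BinnedTrack` stores one vector of non-negative per-bin read counts per
#' chromosome at a fixed bin size, together with the condition label and the
#' total mapped read count (library size).
#'
#' @param counts named list of non-negative numeric vectors, one per
#'   chromosome, in bin order from position 0.
#' @param bin_size bin width in bp (> 0).
#' @param condition condition label, e.g. `"H3K27ac/eA"`.
#' @return object of class `BinnedTrack`.
#' @export
binned_track <- function(counts, bin_size, condition = "track") {
  stopifnot(is.list(counts), !is.null(names(counts)), bin_size > 0)
  if (any(vapply(counts, function(x) any(x < 0), logical(1)))) {
    stop("negative bin counts")
  }
  structure(
    list(counts = counts, bin_size = as.integer(bin_size),
         condition = condition,
         library_size = sum(vapply(counts, sum, numeric(1)))),
    class = "BinnedTrack"
  )
}

#' @export
print.BinnedTrack <- function(x, ...) {
  cat("BinnedTrack", x$condition, "| bin", x$bin_size, "bp |",
      length(x$counts), "chromosome(s) | library",
      format(x$library_size, big.mark = ","), "reads\n")
  invisible(x)
}

#' Read / write a bedGraph-like binned track
#'
#' Four tab-separated columns: chrom, start (0-based), end, count.  All bins
#' must align to the `bin_size` grid; missing bins are zero-filled up to the
#' largest end seen per chromosome.
#'
#' @param path file path.
#' @param bin_size bin width in bp.
#' @param condition condition label.
#' @export
read_bedgraph <- function(path, bin_size, condition = "track") {
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "count"),
                          stringsAsFactors = FALSE)
  if (any(df$start %% bin_size != 0 | df$end - df$start != bin_size)) {
    stop("bins do not align to a ", bin_size, " bp grid")
  }
  counts <- lapply(split(df, df$chrom), function(d) {
    n <- max(d$end) / bin_size
    x <- numeric(n)
    x[d$start / bin_size + 1] <- d$count
    x
  })
  binned_track(counts, bin_size, condition)
}

#' @rdname read_bedgraph
#' @param track a `BinnedTrack` to write.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track$counts)) {
    x <- track$counts[[chrom]]
    starts <- (seq_along(x) - 1L) * track$bin_size
    writeLines(paste(chrom, starts, starts + track$bin_size, x, sep = "\t"),
               con)
  }
  invisible(path)
}

#' Read counts per region with fractional bin weighting
#'
#' The count of a region is the sum of bin counts weighted by the fraction
#' of each bin covered by the region, so the result is additive over any
#' partition of a region and approaches the base-resolution count as bins
#' shrink.
#'
#' @param track a `BinnedTrack`.
#' @param regions `GRanges`; all chromosomes must exist in the track.
#' @return numeric vector of per-region (possibly fractional) counts.
#' @export
quantify <- function(track, regions) {
  chroms <- as.character(seqnames(regions))
  missing <- setdiff(unique(chroms), names(track$counts))
  if (length(missing)) {
    stop("chromosome(s) missing from track: ", paste(missing, collapse = ", "))
  }
  bs <- track$bin_size
  out <- numeric(length(regions))
  s0 <- start(regions) - 1  # 0-based start
  e0 <- end(regions)        # 0-based exclusive end
  for (i in seq_along(regions)) {
    x <- track$counts[[chroms[i]]]
    b0 <- floor(s0[i] / bs)
    b1 <- ceiling(e0[i] / bs) - 1
    bins <- b0:b1
    bstart <- bins * bs
    bend <- bstart + bs
    w <- (pmin(bend, e0[i]) - pmax(bstart, s0[i])) / bs
    cnt <- ifelse(bins + 1 <= length(x) & bins >= 0, x[pmax(bins + 1, 1)], 0)
    out[i] <- sum(cnt * w)
  }
  out
}

#' Log2 fold enrichment of ChIP over genomic input
#'
#' `log2(((chip + p) / chip_lib) / ((input + p) / input_lib))`, i.e. the log
#' two-fold change of the library-size-normalised ChIP count above the
#' genomic input, with a pseudocount `p` on both counts.  Invariant under
#' rescaling both library sizes by a common factor.
#'
#' @param chip,input region counts (vectors recycle).
#' @param chip_lib,input_lib library sizes (> 0).
#' @param pseudocount pseudocount added to both counts (> 0, default 1).
#' @return numeric vector of log2 enrichments.
#' @export
log2_enrichment <- function(chip, input, chip_lib, input_lib,
                            pseudocount = 1) {
  if (any(chip < 0) || any(input < 0)) stop("negative counts")
  if (chip_lib <= 0 || input_lib <= 0) stop("library sizes must be > 0")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  log2(((chip + pseudocount) / chip_lib) /
         ((input + pseudocount) / input_lib))
}

#' Region x condition signal matrix of log2 enrichment
#'
#' @param regions `GRanges`.
#' @param chip_tracks named list of `BinnedTrack`s (ChIP conditions).
#' @param input_track genomic input `BinnedTrack`.
#' @param pseudocount pseudocount for [log2_enrichment()].
#' @return numeric matrix (regions x conditions) with attribute
#'   `kind = "log2_enrichment"`.
#' @export
enrichment_matrix <- function(regions, chip_tracks, input_track,
                              pseudocount = 1) {
  inp <- quantify(input_track, regions)
  vals <- vapply(chip_tracks, function(tr) {
    log2_enrichment(quantify(tr, regions), inp, tr$library_size,
                    input_track$library_size, pseudocount)
  }, numeric(length(regions)))
  vals <- matrix(vals, nrow = length(regions),
                 dimnames = list(
                   if (!is.null(mcols(regions)$name)) mcols(regions)$name
                   else as.character(regions),
                   names(chip_tracks)))
  attr(vals, "kind") <- "log2_enrichment"
  vals
}

#' Threshold a log2-enrichment matrix into a marked/unmarked table
#'
#' A region is "marked" in a condition iff its log2 enrichment over input is
#' at least `threshold`.  Monotone in the threshold.
#'
#' @param sig matrix from [enrichment_matrix()] (kind `log2_enrichment`).
#' @param threshold log2 enrichment cutoff (default 1 = two-fold).
#' @return logical matrix of the same shape.
#' @export
marked_status <- function(sig, threshold = 1) {
  if (!identical(attr(sig, "kind"), "log2_enrichment")) {
    stop("sig must be a log2_enrichment matrix")
  }
  m <- sig >= threshold
  attr(m, "kind") <- NULL
  m
}

#' Per-region signal profile around the midpoint
#'
#' Splits a window of `+/- window` bp around each region midpoint into
#' `n_bins` equal sub-windows (odd `n_bins` so a centre bin exists) and
#' quantifies the track in each; with `input` the cells are per-sub-window
#' log2 enrichments.  Regions whose window extends beyond the chromosome are
#' dropped with a warning.  Column means define the profile-plot curve.
#'
#' @param track ChIP `BinnedTrack`.
#' @param regions `GRanges`.
#' @param window half-window in bp (default 2000).
#' @param n_bins odd number of sub-windows (default 41).
#' @param input optional input `BinnedTrack` for enrichment values.
#' @param pseudocount pseudocount for enrichment.
#' @return matrix (kept regions x n_bins) with attribute `kept` giving the
#'   indices of retained regions.
#' @export
profile_matrix <- function(track, regions, window = 2000L, n_bins = 41L,
                           input = NULL, pseudocount = 1) {
  if (n_bins %% 2 == 0) stop("n_bins must be odd")
  if (window < track$bin_size) stop("window must be >= bin_size")
  mids <- start(region_midpoints(regions)) - 1  # 0-based midpoint
  chroms <- as.character(seqnames(regions))
  chrom_len <- vapply(track$counts, length, integer(1)) * track$bin_size
  keep <- mids - window >= 0 & mids + window <= chrom_len[chroms]
  if (!all(keep)) {
    warning(sum(!keep), " region(s) closer than the window to a chromosome ",
            "edge dropped")
  }
  idx <- which(keep)
  w <- 2 * window / n_bins
  vals <- matrix(NA_real_, length(idx), n_bins)
  inp_vals <- if (!is.null(input)) matrix(NA_real_, length(idx), n_bins)
  for (k in seq_along(idx)) {
    i <- idx[k]
    starts0 <- mids[i] - window + (seq_len(n_bins) - 1) * w
    sub <- GenomicRanges::GRanges(
      chroms[i], IRanges::IRanges(start = round(starts0) + 1,
                                  end = round(starts0 + w)))
    vals[k, ] <- quantify(track, sub)
    if (!is.null(input)) inp_vals[k, ] <- quantify(input, sub)
  }
  if (!is.null(input)) {
    vals <- log2_enrichment(vals, inp_vals, track$library_size,
                            input$library_size, pseudocount)
  }
  attr(vals, "kept") <- idx
  vals
}

#' Input-free Poisson peak caller over a binned track
#'
#' Each bin is tested against a one-sided Poisson null with rate
#' `lambda = max(global mean, local mean in +/- local_halfwidth)`, a dynamic
#' local background in the spirit of input-free MACS.  P-values are BH
#' adjusted across all bins; significant bins additionally require
#' `log2(count / lambda) >= min_log2fc` and are merged when separated by at
#' most one bin.
#'
#' @param track a `BinnedTrack`.
#' @param fdr BH false-discovery cutoff (default 0.05).
#' @param min_log2fc minimum log2 fold over the local rate (default 1).
#' @param local_halfwidth half-width of the local background window in bp.
#' @return `GRanges` of merged peaks (empty for an all-zero track).
#' @export
call_peaks <- function(track, fdr = 0.05, min_log2fc = 1,
                       local_halfwidth = 5000L) {
  if (track$library_size == 0) return(GenomicRanges::GRanges())
  total_bins <- sum(vapply(track$counts, length, integer(1)))
  global <- track$library_size / total_bins
  wbin <- max(1L, round(local_halfwidth / track$bin_size))

  all_p <- list()
  all_lfc <- list()
  for (chrom in names(track$counts)) {
    x <- track$counts[[chrom]]
    n <- length(x)
    # running mean over +/- wbin bins, truncated at the edges
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - wbin, 1L)
    hi <- pmin(seq_len(n) + wbin, n)
    local <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
    lambda <- pmax(global, local)
    all_p[[chrom]] <- stats::ppois(x - 1, lambda, lower.tail = FALSE)
    all_lfc[[chrom]] <- ifelse(x > 0, log2(x / lambda), -Inf)
  }
  padj <- stats::p.adjust(unlist(all_p, use.names = FALSE), method = "BH")
  sig <- padj <= fdr & unlist(all_lfc, use.names = FALSE) >= min_log2fc

  peaks <- GenomicRanges::GRanges()
  offset <- 0L
  bs <- track$bin_size
  for (chrom in names(track$counts)) {
    n <- length(track$counts[[chrom]])
    s <- sig[offset + seq_len(n)]
    offset <- offset + n
    hits <- which(s)
    if (!length(hits)) next
    ir <- IRanges::reduce(IRanges::IRanges(start = (hits - 1L) * bs + 1L,
                                           width = bs),
                          min.gapwidth = bs + 1L)
    peaks <- suppressWarnings(c(
      peaks, GenomicRanges::GRanges(chrom, ir)))
  }
  sort(peaks)
}
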