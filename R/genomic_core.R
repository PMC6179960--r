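#' Read a BED3/BED6 file into a GRanges
#'
#' BED coordinates are 0-based half-open on disk; the returned
#' [GenomicRanges::GRanges] uses the usual 1-based closed convention.
#' Comment (`#`), `track` and `browser` lines are skipped.  Records are
#' sorted by (chrom, start) and de-duplicated on (chrom, start, end).
#'
#' @param path path to a tab-separated BED file.
#' @return a sorted, de-duplicated `GRanges`; column 4, when present, is kept
#'   in metadata column `name`, column 6 as the strand.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  skip <- grepl("^(#|track\\b|browser\\b)", lines) | !nzchar(lines)
  idx <- which(!skip)
  if (length(idx) == 0L) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3L)) {
    stop("malformed BED line ", idx[which(ncols < 3L)[1L]],
         ": fewer than 3 tab-separated columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(!is.finite(start0) | !is.finite(end0) |
                 start0 != floor(start0) | end0 != floor(end0))
  if (length(bad)) {
    stop("malformed BED line ", idx[bad[1L]], ": non-integer coordinates")
  }
  bad <- which(start0 >= end0 | start0 < 0)
  if (length(bad)) {
    stop("malformed BED line ", idx[bad[1L]],
         ": start must satisfy 0 <= start < end")
  }
  name <- if (all(ncols >= 4L)) vapply(fields, `[[`, "", 4L) else NULL
  strand <- if (all(ncols >= 6L)) {
    s <- vapply(fields, `[[`, "", 6L)
    s[!s %in% c("+", "-")] <- "*"
    s
  } else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    strand = strand
  )
  if (!is.null(name)) mcols(gr)$name <- name
  seqlevels(gr) <- sort(seqlevels(gr))
  gr <- sort(gr, ignore.strand = TRUE)
  gr[!duplicated(paste(seqnames(gr), start(gr), end(gr)))]
}

#' Write a GRanges as BED
#'
#' @param gr a `GRanges`; a `name` metadata column is written as column 4.
#' @param path output path.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(
    chrom = as.character(seqnames(gr)),
    start = start(gr) - 1L,
    end = end(gr),
    stringsAsFactors = FALSE
  )
  strands <- as.character(strand(gr))
  has_name <- !is.null(mcols(gr)$name)
  if (has_name || any(strands != "*")) {
    df$name <- if (has_name) mcols(gr)$name else "."
    if (any(strands != "*")) {
      df$score <- 0L
      df$strand <- ifelse(strands == "*", ".", strands)
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Overlapping interval pairs between two peak sets
#'
#' @param a,b `GRanges` peak sets.
#' @param min_bp minimum overlap length in bp (>= 1).
#' @return data.frame with indices into `a` and `b` and the overlap width.
#' @export
overlap_pairs <- function(a, b, min_bp = 1L) {
  if (min_bp < 1) stop("min_bp must be >= 1")
  hits <- GenomicRanges::findOverlaps(a, b, minoverlap = min_bp,
                                      ignore.strand = TRUE)
  ov <- GenomicRanges::pintersect(a[queryHits(hits)], b[subjectHits(hits)],
                                  ignore.strand = TRUE)
  data.frame(
    query = queryHits(hits),
    subject = subjectHits(hits),
    overlap_bp = width(ov)
  )
}

#' Partition per-stage peak sets into stage-unique and shared peaks
#'
#' A peak is unique to its stage iff it overlaps (by at least `min_bp`) no
#' peak of any other stage; otherwise it is shared.  The partition is
#' exhaustive and disjoint within each stage.
#'
#' @param sets named list of `GRanges`, one per stage (>= 2 stages).
#' @param min_bp minimum overlap in bp defining "overlaps".
#' @return named list; per stage a list with elements `unique` and `shared`.
#' @export
stage_unique_sets <- function(sets, min_bp = 1L) {
  if (length(sets) < 2L) stop("need at least 2 stage peak sets")
  if (min_bp < 1) stop("min_bp must be >= 1")
  out <- vector("list", length(sets))
  names(out) <- names(sets)
  for (s in seq_along(sets)) {
    others <- sets[-s]
    other_all <- suppressWarnings(do.call(c, unname(others)))
    if (length(sets[[s]]) == 0L) {
      out[[s]] <- list(unique = sets[[s]], shared = sets[[s]])
      next
    }
    hit <- IRanges::overlapsAny(sets[[s]], other_all,
                                      minoverlap = min_bp,
                                      ignore.strand = TRUE)
    out[[s]] <- list(unique = sets[[s]][!hit], shared = sets[[s]][hit])
  }
  out
}

#' Build a genome annotation from a gene table
#'
#' The gene table is a plain data.frame with one row per gene:
#' `gene_id`, `chrom`, `strand` (`+`/`-`), `start`, `end` (1-based closed
#' transcript span), `exon_starts`, `exon_ends` (comma-separated 1-based
#' coordinates).  The TSS is the span start on `+` and the span end on `-`.
#'
#' @param gene_table data.frame as described above.
#' @param promoter_upstream,promoter_downstream promoter window around the
#'   TSS in bp, strand-aware (defaults 1000/500).
#' @return object of class `GenomeAnnotation`.
#' @export
genome_annotation <- function(gene_table, promoter_upstream = 1000L,
                              promoter_downstream = 500L) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end",
                  "exon_starts", "exon_ends") %in% names(gene_table)))
  if (anyDuplicated(gene_table$gene_id)) stop("duplicate gene_id")
  genes <- GenomicRanges::GRanges(
    seqnames = gene_table$chrom,
    ranges = IRanges::IRanges(gene_table$start, gene_table$end),
    strand = gene_table$strand,
    gene_id = gene_table$gene_id
  )
  tss_pos <- ifelse(gene_table$strand == "+", gene_table$start, gene_table$end)
  tss <- GenomicRanges::GRanges(gene_table$chrom,
                                IRanges::IRanges(tss_pos, width = 1L),
                                strand = gene_table$strand,
                                gene_id = gene_table$gene_id)
  prom <- suppressWarnings(GenomicRanges::promoters(
    tss, upstream = promoter_upstream, downstream = promoter_downstream))
  prom <- GenomicRanges::trim(prom)
  es <- strsplit(as.character(gene_table$exon_starts), ",", fixed = TRUE)
  ee <- strsplit(as.character(gene_table$exon_ends), ",", fixed = TRUE)
  nex <- lengths(es)
  exons <- GenomicRanges::GRanges(
    rep(gene_table$chrom, nex),
    IRanges::IRanges(as.integer(unlist(es)), as.integer(unlist(ee))),
    gene_id = rep(gene_table$gene_id, nex)
  )
  structure(
    list(genes = genes, tss = tss, promoters = prom, exons = exons,
         promoter_window = c(upstream = promoter_upstream,
                             downstream = promoter_downstream)),
    class = "GenomeAnnotation"
  )
}

#' Read / write the gene table format used by [genome_annotation()]
#' @param path file path.
#' @return data.frame (for the reader).
#' @export
read_gene_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(exon_starts = "character",
                                   exon_ends = "character"))
}

#' @rdname read_gene_table
#' @param gene_table data.frame to write.
#' @export
write_gene_table <- function(gene_table, path) {
  utils::write.table(gene_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Integer midpoint of a region: floor((start0 + end0) / 2) in 0-based
# coordinates, returned as a width-1 GRanges in 1-based coordinates.
region_midpoints <- function(gr) {
  mid0 <- floor((start(gr) - 1 + end(gr)) / 2)
  GenomicRanges::GRanges(seqnames(gr), IRanges::IRanges(mid0 + 1L, width = 1L))
}

#' Annotate regions as promoter / exon / intron / intergenic
#'
#' The category is decided by the region midpoint with precedence
#' promoter > exon > intron > intergenic.  Midpoints on chromosomes absent
#' from the annotation fall back to `intergenic` with a warning.
#'
#' @param gr regions (`GRanges`).
#' @param ann a `GenomeAnnotation`.
#' @return factor with levels promoter, exon, intron, intergenic.
#' @export
annotate_region <- function(gr, ann) {
  stopifnot(inherits(ann, "GenomeAnnotation"))
  mids <- region_midpoints(gr)
  known <- as.character(seqnames(mids)) %in%
    as.character(unique(seqnames(ann$genes)))
  if (!all(known)) {
    warning(sum(!known), " region(s) on chromosomes absent from the ",
            "annotation; classified as intergenic")
  }
  cat_lv <- c("promoter", "exon", "intron", "intergenic")
  out <- rep("intergenic", length(gr))
  in_prom <- IRanges::overlapsAny(mids, ann$promoters,
                                        ignore.strand = TRUE)
  in_exon <- IRanges::overlapsAny(mids, ann$exons, ignore.strand = TRUE)
  in_gene <- IRanges::overlapsAny(mids, ann$genes, ignore.strand = TRUE)
  out[in_gene] <- "intron"
  out[in_exon] <- "exon"
  out[in_prom] <- "promoter"
  factor(out, levels = cat_lv)
}

#' Assign each region to its nearest gene under the 50-kb rule
#'
#' Regions whose midpoint lies in a promoter, exon or intron are assigned to
#' the host gene (containment beats distance).  Intergenic regions are
#' assigned to the gene with the nearest TSS when the midpoint-to-TSS
#' distance is strictly less than `max_tss_dist`, else left unassigned.
#' Ties are broken by the lexicographically smallest `gene_id`; assignment
#' never crosses chromosomes.
#'
#' @param gr regions (`GRanges`).
#' @param ann a `GenomeAnnotation`.
#' @param max_tss_dist maximum midpoint-to-TSS distance in bp (default 50000).
#' @return character vector of gene ids (`NA` where unassigned).
#' @export
assign_nearest_gene <- function(gr, ann, max_tss_dist = 50000L) {
  stopifnot(inherits(ann, "GenomeAnnotation"))
  if (max_tss_dist <= 0) stop("max_tss_dist must be > 0")
  mids <- region_midpoints(gr)
  category <- suppressWarnings(annotate_region(gr, ann))
  out <- rep(NA_character_, length(gr))

  host_gene <- function(container) {
    hits <- GenomicRanges::findOverlaps(mids, container, ignore.strand = TRUE)
    ids <- tapply(container$gene_id[subjectHits(hits)], queryHits(hits),
                  function(g) sort(g)[1L])
    res <- rep(NA_character_, length(gr))
    res[as.integer(names(ids))] <- as.character(ids)
    res
  }
  prom_host <- host_gene(ann$promoters)
  exon_host <- host_gene(ann$exons)
  gene_host <- host_gene(ann$genes)
  sel <- category == "promoter"
  out[sel] <- prom_host[sel]
  sel <- category == "exon"
  out[sel] <- exon_host[sel]
  sel <- category == "intron"
  out[sel] <- gene_host[sel]

  inter <- which(category == "intergenic")
  if (length(inter)) {
    mpos <- start(mids)[inter]
    mchr <- as.character(seqnames(mids))[inter]
    tchr <- as.character(seqnames(ann$tss))
    tpos <- start(ann$tss)
    tid <- ann$tss$gene_id
    for (i in seq_along(inter)) {
      onchr <- which(tchr == mchr[i])
      if (!length(onchr)) next
      d <- abs(tpos[onchr] - mpos[i])
      dmin <- min(d)
      if (dmin < max_tss_dist) {
        cand <- tid[onchr][d == dmin]
        out[inter[i]] <- sort(cand)[1L]
      }
    }
  }
  out
}
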