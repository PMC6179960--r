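test_that("read_bed converts 0-based half-open records and sorts them", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("# a comment",
               "track name=test",
               "chrB\t100\t200\tpk2",
               "chrA\t0\t50\tpk1",
               "",
               "chrA\t0\t50\tpk1_dup"), path)
  gr <- read_bed(path)
  expect_length(gr, 2)
  expect_identical(as.character(seqnames(gr)), c("chrA", "chrB"))
  expect_identical(start(gr), c(1L, 101L))  # +1 shift on start only
  expect_identical(end(gr), c(50L, 200L))
  expect_identical(mcols(gr)$name, c("pk1", "pk2"))
})

test_that("read_bed rejects malformed records with a line number", {
  bad1 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrA\t10\t20", "chrA\t5"), bad1)
  expect_error(read_bed(bad1), "line 2.*fewer than 3")

  bad2 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrA\t10\t20", "chrA\t1.5\t9"), bad2)
  expect_error(read_bed(bad2), "line 2.*non-integer")

  bad3 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrA\t30\t20"), bad3)
  expect_error(read_bed(bad3), "start must satisfy")

  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines("# only comments", empty)
  expect_length(read_bed(empty), 0)
})

test_that("write_bed / read_bed round-trips coordinates exactly", {
  gr <- random_regions(42, 60)
  mcols(gr)$name <- sprintf("r%02d", seq_along(gr))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(gr, path)
  back <- read_bed(path)
  srt <- gr
  GenomeInfoDb::seqlevels(srt) <- sort(GenomeInfoDb::seqlevels(srt))
  srt <- sort(srt, ignore.strand = TRUE)
  srt <- srt[!duplicated(paste(seqnames(srt), start(srt), end(srt)))]
  expect_identical(start(back), start(srt))
  expect_identical(end(back), end(srt))
  expect_identical(as.character(seqnames(back)), as.character(seqnames(srt)))
  # disk format is 0-based half-open (rows are written in input order)
  raw <- read.delim(path, header = FALSE)
  ord <- order(raw$V1, raw$V2, raw$V3)
  expect_identical(raw$V2[ord] + 1L, start(back))
  expect_identical(raw$V3[ord], end(back))
})

test_that("overlap_pairs matches the quadratic oracle on random sets", {
  for (seed in c(1, 2, 3, 4, 5)) {
    a <- random_regions(seed, 40)
    b <- random_regions(seed + 100, 40)
    for (min_bp in c(1L, 25L, 80L)) {
      got <- overlap_pairs(a, b, min_bp)
      got <- got[order(got$query, got$subject), , drop = FALSE]
      want <- oracle_overlaps(a, b, min_bp)
      expect_equal(unname(as.matrix(got)), unname(as.matrix(want)),
                   ignore_attr = TRUE)
    }
  }
})

test_that("overlap width never exceeds either interval's width", {
  a <- random_regions(7, 50)
  b <- random_regions(8, 50)
  ov <- overlap_pairs(a, b)
  expect_true(all(ov$overlap_bp <= width(a)[ov$query]))
  expect_true(all(ov$overlap_bp <= width(b)[ov$subject]))
  expect_true(all(ov$overlap_bp >= 1))
})

test_that("stage_unique_sets partitions each stage exhaustively", {
  s1 <- GRanges("chr1", IRanges(c(1, 100, 300), width = 50))
  s2 <- GRanges("chr1", IRanges(c(120, 500), width = 50))
  s3 <- GRanges("chr1", IRanges(c(1000), width = 50))
  res <- stage_unique_sets(list(a = s1, b = s2, c = s3))
  expect_identical(start(res$a$unique), c(1L, 300L))
  expect_identical(start(res$a$shared), 100L)
  expect_identical(start(res$b$unique), 500L)
  expect_identical(start(res$c$unique), 1000L)
  for (st in res) {
    expect_length(intersect(start(st$unique), start(st$shared)), 0)
  }
  # raising min_bp makes small overlaps not count
  res2 <- stage_unique_sets(list(a = s1, b = s2, c = s3), min_bp = 40L)
  expect_length(res2$a$shared, 0)
  expect_error(stage_unique_sets(list(a = s1)), "at least 2")
})

test_that("genome_annotation builds strand-aware TSS and promoters", {
  ann <- genome_annotation(toy_gene_table())
  expect_s3_class(ann, "GenomeAnnotation")
  # + gene: TSS at span start; - gene: TSS at span end
  expect_identical(start(ann$tss), c(2001L, 14000L, 5001L))
  # promoter = [tss - 1000, tss + 499] on +, mirrored on -
  expect_identical(start(ann$promoters)[1], 1001L)
  expect_identical(end(ann$promoters)[1], 2500L)
  expect_identical(start(ann$promoters)[2], 13501L)
  expect_identical(end(ann$promoters)[2], 15000L)
  expect_error(genome_annotation(rbind(toy_gene_table(), toy_gene_table())),
               "duplicate")
})

test_that("gene table round-trips through disk", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(toy_gene_table(), path)
  back <- read_gene_table(path)
  expect_identical(back, toy_gene_table())
})

test_that("annotate_region applies midpoint precedence", {
  ann <- genome_annotation(toy_gene_table())
  regions <- GRanges("chrA", IRanges(
    start = c(1500, 3000, 3100, 50000),
    end   = c(1700, 3002, 3300, 50100)))
  # midpoints: 1600 (promoter), 3001 (intron gap 2501..3500), 3200 (intron),
  # 50050 (intergenic)
  got <- annotate_region(regions, ann)
  expect_identical(as.character(got),
                   c("promoter", "intron", "intron", "intergenic"))
  # a midpoint inside exon 2 of gA1
  ex <- annotate_region(GRanges("chrA", IRanges(3600, 3700)), ann)
  expect_identical(as.character(ex), "exon")
  # promoter beats exon where they overlap (start of gA1)
  pr <- annotate_region(GRanges("chrA", IRanges(2050, 2060)), ann)
  expect_identical(as.character(pr), "promoter")
  # an off-annotation chromosome warns (plus a seqlevel warning from the
  # underlying combine)
  warns <- capture_warnings(annotate_region(GRanges("chrZ", IRanges(5, 10)),
                                            ann))
  expect_true(any(grepl("absent", warns)))
})

test_that("assign_nearest_gene: containment beats distance, 50-kb rule is strict", {
  ann <- genome_annotation(toy_gene_table())
  # midpoint inside gA2's intron although gA1's TSS could be closer
  inside <- GRanges("chrA", IRanges(12700, 12800))
  expect_identical(assign_nearest_gene(inside, ann), "gA2")
  # intergenic midpoint nearer gA2's TSS (at 14000)
  inter <- GRanges("chrA", IRanges(19950, 20050))  # midpoint 20000
  expect_identical(assign_nearest_gene(inter, ann), "gA2")
  # strictly-less-than distance rule at exactly max_tss_dist
  far <- GRanges("chrA", IRanges(63950, 64050))  # midpoint 64000, d = 50000
  expect_identical(assign_nearest_gene(far, ann, max_tss_dist = 50000L),
                   NA_character_)
  expect_identical(assign_nearest_gene(far, ann, max_tss_dist = 50001L),
                   "gA2")
  # never crosses chromosomes
  other <- GRanges("chrB", IRanges(6900, 7000))
  expect_identical(assign_nearest_gene(other, ann), "gB1")
})

test_that("assign_nearest_gene breaks exact TSS ties lexicographically", {
  gt <- data.frame(
    gene_id = c("gZ", "gA"), chrom = "chr1", strand = "+",
    start = c(1000L, 3000L), end = c(1500L, 3500L),
    exon_starts = c("1000", "3000"), exon_ends = c("1500", "3500"),
    stringsAsFactors = FALSE)
  ann <- genome_annotation(gt, promoter_upstream = 10L,
                           promoter_downstream = 10L)
  # midpoint 2000 is equidistant (1000 bp) from both TSS
  mid <- GRanges("chr1", IRanges(1950, 2050))
  expect_identical(assign_nearest_gene(mid, ann), "gA")
})
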