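toy_pwm <- function(seed = 21, w = 5, dom = 0.85) {
  withr::with_seed(seed, {
    cons <- sample.int(4, w, replace = TRUE)
    mat <- matrix((1 - dom) / 3, w, 4)
    mat[cbind(seq_len(w), cons)] <- dom
    pwm(mat, "toy", "ToyTF")
  })
}

test_that("pwm validates its matrix and floors probabilities", {
  expect_error(pwm(matrix(1, 2, 3), "x"), "4 columns")
  expect_error(pwm(matrix(c(0.5, 0.4, 0.05, 0.04), 1), "x"), "sum to 1")
  p <- pwm(matrix(c(1, 0, 0, 0), 1), "x")
  expect_equal(unname(p$log_odds[1, "A"]), log2(1 / 0.25))
  expect_equal(unname(p$log_odds[1, "C"]), log2(1e-3 / 0.25))  # floored
  expect_true(all(is.finite(p$log_odds)))
})

test_that("PWM library round-trips through disk", {
  lib <- list(toy = toy_pwm(), other = toy_pwm(22, w = 8))
  lib$other$motif_id <- "other"
  path <- withr::local_tempfile(fileext = ".txt")
  write_pwms(lib, path)
  back <- read_pwms(path)
  expect_identical(names(back), c("toy", "other"))
  expect_equal(back$toy$matrix, lib$toy$matrix, tolerance = 1e-5)
  expect_identical(back$toy$tf_name, "ToyTF")
  expect_equal(back$other$log_odds, lib$other$log_odds, tolerance = 1e-4)
})

test_that("calibrate_threshold matches exhaustive enumeration", {
  for (seed in c(31, 32)) {
    p <- toy_pwm(seed, w = 5)
    for (pv in c(1e-2, 1e-3)) {
      thr <- calibrate_threshold(p, pvalue = pv)
      # attained tail is exact and <= requested
      expect_equal(attr(thr, "tail_prob"), oracle_tail(p, thr),
                   tolerance = 1e-12)
      expect_lte(attr(thr, "tail_prob"), pv)
      # one discretisation step lower would exceed the requested p-value
      expect_gt(oracle_tail(p, thr - 0.005), pv)
    }
  }
})

test_that("calibrate_threshold warns when the p-value is unattainable", {
  p <- pwm(matrix(0.25, 2, 4), "flat")
  expect_warning(thr <- calibrate_threshold(p, pvalue = 1e-9), "attainable")
  expect_equal(as.numeric(thr), 0)  # flat PWM scores are identically zero
})

test_that("threshold tail agrees with Monte Carlo within 3 standard errors", {
  p <- toy_pwm(33, w = 8)
  thr <- calibrate_threshold(p, pvalue = 1e-3)
  n <- 200000L
  hits <- withr::with_seed(99, {
    codes <- matrix(sample.int(4, n * p$width, replace = TRUE), n, p$width)
    sc <- numeric(n)
    for (j in seq_len(p$width)) sc <- sc + p$log_odds[j, ][codes[, j]]
    # discretise like the calibration so only sampling noise remains
    mean(round(sc / 0.005) * 0.005 >= thr)
  })
  tail <- attr(thr, "tail_prob")
  se <- sqrt(tail * (1 - tail) / n)
  expect_lt(abs(hits - tail), 3 * se + 1e-12)
})

test_that("scan_sequence matches the naive oracle on both strands", {
  p <- toy_pwm(34, w = 6)
  thr <- calibrate_threshold(p, pvalue = 5e-3)
  for (seed in c(41, 42, 43)) {
    s <- random_dna(seed, 400)
    got <- scan_sequence(p, s, thr)
    want <- oracle_scan(p, s, thr)
    expect_equal(got$pos, want$pos)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-10)
  }
})

test_that("scan_sequence finds a planted instance and its reverse complement", {
  p <- toy_pwm(35, w = 8)
  cons <- paste(c("A", "C", "G", "T")[apply(p$matrix, 1, which.max)],
                collapse = "")
  thr <- calibrate_threshold(p, pvalue = 1e-4)
  left <- random_dna(51, 50)
  right <- random_dna(52, 50)
  fwd <- scan_sequence(p, paste0(left, cons, right), thr)
  expect_true(51 %in% fwd$pos)
  expect_identical(fwd$strand[fwd$pos == 51], "+")
  rc <- scan_sequence(p, paste0(left, revcomp_str(cons), right), thr)
  expect_true(51 %in% rc$pos)
  expect_identical(rc$strand[rc$pos == 51], "-")
})

test_that("scan_sequence skips windows containing N and short sequences", {
  p <- toy_pwm(36, w = 6)
  s <- paste0(substr(random_dna(53, 20), 1, 10), "N",
              substr(random_dna(54, 20), 1, 10))
  got <- scan_sequence(p, s, -100)
  expect_false(any(got$pos %in% 6:11))  # windows covering the N
  expect_identical(nrow(scan_sequence(p, "ACG", 0)), 0L)
})

test_that("gc_content and region_sequences agree with direct computation", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AAGGCCTTAA"))
  r <- GRanges("chr1", IRanges(c(1, 3), c(4, 8)))
  expect_equal(gc_content(r, genome), c(0.5, 4 / 6))
  expect_error(gc_content(GRanges("chrX", IRanges(1, 2)), genome),
               "missing")
})

test_that("gc_matched_background matches the target GC profile", {
  genome <- withr::with_seed(61, {
    Biostrings::DNAStringSet(c(chr1 = paste(
      sample(c("A", "C", "G", "T"), 200000,
             replace = TRUE, prob = c(0.3, 0.2, 0.2, 0.3)),
      collapse = "")))
  })
  targets <- GRanges("chr1", IRanges(seq(1000, 40000, by = 1000),
                                     width = 300))
  pool <- GRanges("chr1", IRanges(seq(50000, 199000, by = 400), width = 300))
  bg <- gc_matched_background(targets, pool, genome, ratio = 2, seed = 5)
  expect_equal(length(bg), 2 * length(targets))
  expect_false(any(IRanges::overlapsAny(bg, targets)))
  expect_lt(abs(mean(gc_content(bg, genome)) -
                  mean(gc_content(targets, genome))), 0.02)
  bg2 <- gc_matched_background(targets, pool, genome, ratio = 2, seed = 5)
  expect_identical(start(bg), start(bg2))
})

test_that("motif_enrichment's hypergeometric p matches direct summation", {
  # small sets so the alternative computation is a plain dhyper sum
  genome <- withr::with_seed(62, {
    Biostrings::DNAStringSet(c(chr1 = random_dna(63, 60000)))
  })
  p <- toy_pwm(37, w = 7)
  thr <- calibrate_threshold(p, pvalue = 2e-3)
  targets <- GRanges("chr1", IRanges(seq(1, 12000, by = 1200), width = 250))
  bg <- GRanges("chr1", IRanges(seq(20000, 37000, by = 1200), width = 250))
  expect_lte(length(targets) + length(bg), 25)
  res <- motif_enrichment(targets, bg, genome, list(toy = p),
                          thresholds = c(toy = thr))
  th <- res$n_target_hit
  bh <- res$n_bg_hit
  nt <- length(targets)
  nb <- length(bg)
  direct <- oracle_phyper_tail(th, th + bh, nt + nb - th - bh, nt)
  expect_equal(res$p, direct, tolerance = 1e-12)
  # hand-check the hit counts with the scanner
  seqs <- astroprime:::region_sequences(genome, targets)
  expect_equal(th, sum(vapply(seqs, function(s)
    nrow(scan_sequence(p, s, thr)) > 0, logical(1))))
})

test_that("motif_enrichment flags planted motifs and spares decoys", {
  ds <- small_dataset()
  truth <- ds$truth
  ea <- truth[truth$class == "eA_unique", ]
  targets <- GRanges(ea$chrom, IRanges(ea$start, ea$end))
  nv <- truth[truth$class == "never_active", ]
  bg <- GRanges(nv$chrom, IRanges(nv$start, nv$end))
  res <- motif_enrichment(targets, bg, ds$genome, ds$pwms,
                          thresholds = ds$thresholds)
  expect_true(all(c("M_eA1", "M_eA2") %in% res$motif_id[res$enriched]))
  expect_false(any(grepl("^decoy", res$motif_id[res$enriched])))
  binom <- motif_enrichment(targets, bg, ds$genome,
                            ds$pwms[c("M_eA1", "decoy_01")],
                            thresholds = ds$thresholds,
                            method = "binomial")
  expect_lt(binom$p[binom$motif_id == "M_eA1"], 1e-6)
})

test_that("nominate_tfs filters unexpressed TFs and keeps unmappable motifs", {
  enr <- function(ids, enriched) {
    data.frame(motif_id = ids, tf_name = ids, n_target = 10,
               n_target_hit = 9, n_bg = 20, n_bg_hit = 1,
               odds_ratio = 10, p = c(1e-8, 1e-6, 1e-4)[seq_along(ids)],
               fdr = 1e-4, enriched = enriched, stringsAsFactors = FALSE)
  }
  astro <- enr(c("m1", "m2", "m3"), c(TRUE, TRUE, TRUE))
  neuro <- enr(c("m3", "mx", "my"), c(TRUE, FALSE, FALSE))
  motif2tf <- data.frame(motif_id = c("m1", "m2"), gene = c("tfA", "tfB"),
                         stringsAsFactors = FALSE)
  expr <- matrix(c(5, 0), 2, 1, dimnames = list(c("tfA", "tfB"), "stage1"))
  res <- nominate_tfs(astro, neuro, motif2tf, expr, "stage1")
  expect_identical(res$common, "m3")
  expect_identical(res$candidates$motif_id, "m1")  # tfB not expressed
  expect_identical(res$candidates$tf_gene, "tfA")
  # an unmapped motif is retained and flagged
  motif2tf2 <- motif2tf[1, , drop = FALSE]
  res2 <- nominate_tfs(astro, neuro, motif2tf2, expr, "stage1")
  expect_true("m2" %in% res2$candidates$motif_id)
  expect_true(res2$candidates$unmappable[res2$candidates$motif_id == "m2"])
  expect_identical(res2$candidates$rank, seq_len(nrow(res2$candidates)))
})
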