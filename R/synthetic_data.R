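#' Simulation configuration for the synthetic differentiation dataset
#'
#' Defines a toy two-lineage differentiation system: a shared progenitor
#' genome with three astroglial stages (aNPC, eA, lA) and three neuronal
#' stages (nNPC, eN, lN), regulatory elements with planted chromatin-state
#' trajectories, planted TF motifs in stage-specific active enhancers,
#' expression counts coupled to enhancer activation, and TF-knockdown
#' experiments.  The genome is organised in 20-kb units of one gene plus at
#' most one enhancer, so every stage-unique enhancer lies 5-7.5 kb from its
#' linked gene's TSS and that gene is its nearest TSS.
#'
#' @param seed root RNG seed; every generator draws named substreams from it.
#' @param n_chroms number of chromosomes.
#' @param chrom_len chromosome length in bp.
#' @param n_genes total genes (one per 20-kb unit; must allow
#'   `8 * n_per_class` units).
#' @param n_per_class enhancers per class (six stage-unique classes plus
#'   constitutive and never-active).
#' @param bin_size ChIP track bin width in bp.
#' @param chip_depth reads per ChIP/input condition.
#' @param enrichment_fold_active H3K27ac fold over background at active
#'   elements (H3K27ac also marks acetyl-only elements).
#' @param enrichment_fold_primed H3K4me1 fold at primed and active elements.
#' @param nb_dispersion negative-binomial dispersion of expression counts.
#' @param expr_boost expression fold at genes whose linked enhancer is
#'   active at a stage.
#' @param kd_effect fraction of H3K27ac retained at motif-bearing target
#'   sites after knocking down a chromatin-remodeling TF.
#' @param kd_expr_effect fraction of target-gene expression retained after
#'   a TF knockdown.  The default (strong direct-target repression) is
#'   chosen so a two-group negative-binomial test at 3 vs 3 replicates with
#'   dispersion `nb_dispersion` detects nearly all targets: the planted
#'   |log2 fold| of ~2.7 is about 7 standard errors, whereas a fold equal
#'   to `1 / expr_boost` would sit near 3.5 standard errors and be mostly
#'   missed at a 10 percent FDR.
#' @param enhancer_width enhancer width in bp.
#' @param n_decoys shuffled decoy PWMs added to the motif library.
#' @param motif_pvalue null p-value at which motif thresholds are calibrated.
#' @param cobound_targets number of eA enhancers carrying both remodeling
#'   TFs' motifs (planted two-TF target overlap).
#' @param n_reps expression replicates per condition.
#' @param baseline_log_mean,baseline_log_sd log-normal baseline expression.
#' @param size_factor_jitter relative spread of per-sample depth.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 4L,
                       chrom_len = 6.2e6,
                       n_genes = 1200L,
                       n_per_class = 150L,
                       bin_size = 200L,
                       chip_depth = 2e6,
                       enrichment_fold_active = 8,
                       enrichment_fold_primed = 6,
                       nb_dispersion = 0.1,
                       expr_boost = 2.5,
                       kd_effect = 0.4,
                       kd_expr_effect = 0.15,
                       enhancer_width = 600L,
                       n_decoys = 20L,
                       motif_pvalue = 1e-4,
                       cobound_targets = 47L,
                       n_reps = 3L,
                       baseline_log_mean = log(150),
                       baseline_log_sd = 1,
                       size_factor_jitter = 0.2) {
  cfg <- as.list(environment())
  cfg$unit_len <- 20000L
  if (cfg$enrichment_fold_active <= 1 || cfg$enrichment_fold_primed <= 1) {
    stop("enrichment folds must be > 1")
  }
  if (cfg$expr_boost <= 1) stop("expr_boost must be > 1")
  if (cfg$chip_depth <= 0) stop("chip_depth must be > 0")
  if (cfg$kd_effect <= 0 || cfg$kd_effect >= 1) {
    stop("kd_effect must be in (0, 1)")
  }
  if (cfg$kd_expr_effect <= 0 || cfg$kd_expr_effect >= 1) {
    stop("kd_expr_effect must be in (0, 1)")
  }
  if (cfg$n_genes %% cfg$n_chroms != 0) {
    stop("n_genes must be a multiple of n_chroms")
  }
  units_per_chrom <- cfg$n_genes / cfg$n_chroms
  if (units_per_chrom * cfg$unit_len > cfg$chrom_len) {
    stop("genes do not fit at 20 kb spacing; increase chrom_len or reduce ",
         "n_genes")
  }
  if (8L * cfg$n_per_class > cfg$n_genes) {
    stop("need n_genes >= 8 * n_per_class gene units for the enhancer ",
         "classes")
  }
  if (cfg$cobound_targets > cfg$n_per_class) {
    stop("cobound_targets cannot exceed n_per_class")
  }
  structure(cfg, class = "sim_config")
}

stages_astro <- function() c("aNPC", "eA", "lA")
stages_neuro <- function() c("nNPC", "eN", "lN")

# Truth state trajectories per enhancer class; priming always precedes
# activation within a lineage, and the two lineages share progenitor
# chromatin except at neuro-class enhancers.
class_states <- function() {
  list(
    aNPC_unique = list(astro = c("active", "none", "none"),
                       neuro = c("active", "none", "none")),
    eA_unique   = list(astro = c("primed", "active", "primed"),
                       neuro = c("primed", "primed", "primed")),
    lA_unique   = list(astro = c("none", "primed", "active"),
                       neuro = c("none", "none", "none")),
    nNPC_unique = list(astro = c("none", "none", "none"),
                       neuro = c("active", "none", "none")),
    eN_unique   = list(astro = c("primed", "primed", "primed"),
                       neuro = c("primed", "active", "primed")),
    lN_unique   = list(astro = c("none", "none", "none"),
                       neuro = c("none", "primed", "active")),
    constitutive = list(astro = rep("active", 3),
                        neuro = rep("active", 3)),
    never_active = list(astro = rep("primed", 3),
                        neuro = rep("primed", 3))
  )
}

#' Simulate the toy genome and gene models
#'
#' I.i.d. uniform-base chromosomes; one gene per 20-kb unit (2.4-kb span,
#' two 600-bp exons flanking a 1.2-kb intron, random strand).
#' Deterministic given the config seed.
#'
#' @param cfg a `sim_config`.
#' @return list: `genome` (`DNAStringSet`), `gene_table` (see
#'   [genome_annotation()]), `units` (unit bookkeeping).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  genome <- with_substream(cfg$seed, "genome", {
    seqs <- lapply(chroms, function(ch) {
      paste(sample(c("A", "C", "G", "T"), cfg$chrom_len, replace = TRUE),
            collapse = "")
    })
    s <- Biostrings::DNAStringSet(unlist(seqs))
    names(s) <- chroms
    s
  })
  upc <- cfg$n_genes / cfg$n_chroms
  unit <- seq_len(cfg$n_genes)
  chrom <- rep(chroms, each = upc)
  unit_start <- rep((seq_len(upc) - 1L) * cfg$unit_len, cfg$n_chroms)
  strand <- with_substream(cfg$seed, "gene_strand",
                           sample(c("+", "-"), cfg$n_genes, replace = TRUE))
  gstart <- unit_start + 2001L  # 1-based
  gend <- gstart + 2399L
  tss <- ifelse(strand == "+", gstart, gend)
  gene_id <- sprintf("gene_%04d", unit)
  gene_table <- data.frame(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = gstart, end = gend,
    exon_starts = paste(gstart, gend - 599L, sep = ","),
    exon_ends = paste(gstart + 599L, gend, sep = ","),
    stringsAsFactors = FALSE
  )
  units <- data.frame(unit = unit, chrom = chrom, unit_start = unit_start,
                      gene_id = gene_id, strand = strand, tss = tss,
                      stringsAsFactors = FALSE)
  list(genome = genome, gene_table = gene_table, units = units)
}

# Sharp synthetic PWM: dominant base probability 0.85 per position.
make_pwm <- function(consensus_codes, motif_id, tf_name = motif_id) {
  w <- length(consensus_codes)
  mat <- matrix(0.05, w, 4)
  mat[cbind(seq_len(w), consensus_codes)] <- 0.85
  pwm(mat, motif_id, tf_name)
}

# Sample a motif instance from a PWM, retrying until it scores above the
# threshold on the forward strand.
sample_instance <- function(p, threshold, max_tries = 50L) {
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(max_tries)) {
    codes <- apply(p$matrix, 1, function(pr) sample.int(4, 1, prob = pr))
    score <- sum(p$log_odds[cbind(seq_len(p$width), codes)])
    if (score >= threshold) return(paste(bases[codes], collapse = ""))
  }
  # fall back to the consensus, which always scores maximally
  paste(bases[apply(p$matrix, 1, which.max)], collapse = "")
}

#' Plant enhancers, truth-state trajectories and motifs
#'
#' Assigns each gene unit one enhancer class (six stage-unique classes,
#' constitutive, never-active; remaining units get none), places the
#' enhancer 5-7.5 kb from the unit gene's TSS (intergenic, nearest TSS =
#' linked gene), embeds consensus-like motif instances at stage-unique
#' enhancers, and builds the PWM library (seven planted stage motifs, of
#' which three are the knockdown TFs, plus shuffled decoys).  Among the
#' eA enhancers `cobound_targets` carry both remodeling TFs' motifs.
#'
#' @param cfg a `sim_config`.
#' @param sim output of [simulate_genome()]; its genome is modified in the
#'   returned object (motif instances written into the sequence).
#' @return list: `genome` (with motifs embedded), `enhancers` (`GRanges`),
#'   `truth` (data.frame, one row per enhancer), `pwms`, `thresholds`,
#'   `tf_table`, `motif2tf`, `gene_table`, `units`.
#' @export
plant_enhancers <- function(cfg, sim) {
  states <- class_states()
  classes <- names(states)
  n_units <- nrow(sim$units)
  assign <- with_substream(cfg$seed, "class_assignment", {
    lab <- c(rep(classes, each = cfg$n_per_class),
             rep(NA_character_, n_units - 8L * cfg$n_per_class))
    sample(lab)
  })

  # planted motif library: one motif per stage-unique class
  stage_motifs <- c(aNPC_unique = "M_aNPC", eA_unique = "M_eA1",
                    lA_unique = "M_lA", nNPC_unique = "M_nNPC",
                    eN_unique = "M_eN", lN_unique = "M_lN")
  tf_genes <- c(M_eA1 = "Tfa", M_eA2 = "Tfb", M_lA = "Tfc",
                M_aNPC = "Tfd", M_nNPC = "Tfe", M_eN = "Tff", M_lN = "Tfg")
  pwms <- with_substream(cfg$seed, "pwms", {
    ids <- c("M_eA1", "M_eA2", "M_lA", "M_aNPC", "M_nNPC", "M_eN", "M_lN")
    planted <- lapply(ids, function(id) {
      make_pwm(sample.int(4, 10, replace = TRUE), id, tf_genes[[id]])
    })
    names(planted) <- ids
    decoys <- lapply(seq_len(cfg$n_decoys), function(j) {
      src <- planted[[(j - 1L) %% length(planted) + 1L]]
      mat <- src$matrix[sample(nrow(src$matrix)), sample(4)]
      pwm(mat, sprintf("decoy_%02d", j))
    })
    names(decoys) <- vapply(decoys, `[[`, "", "motif_id")
    c(planted, decoys)
  })
  thresholds <- vapply(pwms, calibrate_threshold, numeric(1),
                       pvalue = cfg$motif_pvalue)

  enh_units <- which(!is.na(assign))
  cls <- assign[enh_units]
  u <- sim$units[enh_units, ]
  half <- cfg$enhancer_width / 2
  mid <- with_substream(cfg$seed, "enhancer_position",
                        u$tss + round(stats::runif(length(enh_units),
                                                   5000, 7500)))
  enh <- GenomicRanges::GRanges(u$chrom,
                                IRanges::IRanges(mid - half + 1L,
                                                 mid + half))
  enh_id <- sprintf("enh_%04d", seq_along(enh_units))
  mcols(enh)$name <- enh_id
  mcols(enh)$class <- cls

  # motif assignment: eA enhancers split between the two remodeling TFs
  # with a planted co-bound overlap; other stage-unique classes carry
  # their single class motif
  motifs <- vector("list", length(enh_units))
  iA <- which(cls == "eA_unique")
  n_co <- cfg$cobound_targets
  n_single <- length(iA) - n_co
  n_a_only <- ceiling(n_single / 2)
  pick <- with_substream(cfg$seed, "cobound_assignment", sample(iA))
  motifs[pick[seq_len(n_co)]] <- list(c("M_eA1", "M_eA2"))
  motifs[pick[n_co + seq_len(n_a_only)]] <- list("M_eA1")
  motifs[pick[(n_co + n_a_only + 1):length(pick)]] <- list("M_eA2")
  for (k in setdiff(names(stage_motifs), "eA_unique")) {
    motifs[cls == k] <- list(stage_motifs[[k]])
  }
  motifs[cls %in% c("constitutive", "never_active")] <- list(character(0))

  # embed instances centred in the enhancer
  inst_tab <- with_substream(cfg$seed, "motif_instances", {
    rows <- list()
    for (i in seq_along(enh_units)) {
      ms <- motifs[[i]]
      if (!length(ms)) next
      offs <- if (length(ms) == 1) -5L else c(-12L, 2L)  # non-overlapping
      for (j in seq_along(ms)) {
        p <- pwms[[ms[j]]]
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = u$chrom[i], start = mid[i] + offs[j], width = p$width,
          inst = sample_instance(p, thresholds[[ms[j]]]),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  seqs <- lapply(names(sim$genome), function(ch) {
    tb <- inst_tab[inst_tab$chrom == ch, , drop = FALSE]
    s <- sim$genome[[ch]]
    if (nrow(tb)) {
      tb <- tb[order(tb$start), , drop = FALSE]
      s <- Biostrings::replaceAt(s,
                                 IRanges::IRanges(tb$start, width = tb$width),
                                 tb$inst)
    }
    as.character(s)
  })
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- names(sim$genome)

  st <- states[match(cls, classes)]
  truth <- data.frame(
    enh_id = enh_id, chrom = u$chrom,
    start = start(enh), end = end(enh), class = cls,
    linked_gene = ifelse(cls %in% names(stage_motifs), u$gene_id,
                         NA_character_),
    motifs = vapply(motifs, paste, "", collapse = ","),
    tss_dist = abs(mid - u$tss),
    stringsAsFactors = FALSE
  )
  for (j in 1:3) {
    truth[[paste0("astro_", stages_astro()[j])]] <-
      vapply(st, function(x) x$astro[j], "")
    truth[[paste0("neuro_", stages_neuro()[j])]] <-
      vapply(st, function(x) x$neuro[j], "")
  }

  # knockdown TF table: two remodeling eA TFs, one non-remodeling lA TF
  tf_table <- data.frame(
    tf_gene = c("Tfa", "Tfb", "Tfc"),
    motif_id = c("M_eA1", "M_eA2", "M_lA"),
    stage = c("eA", "eA", "lA"),
    lineage = "astro",
    remodeling = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  motif2tf <- data.frame(motif_id = names(tf_genes),
                         gene = unname(tf_genes),
                         stringsAsFactors = FALSE)

  # rename the TF genes in the gene table: use genes of never-active units
  gene_table <- sim$gene_table
  units <- sim$units
  na_units <- enh_units[cls == "never_active"]
  tf_unit <- na_units[seq_along(tf_genes)]
  for (j in seq_along(tf_genes)) {
    old <- units$gene_id[units$unit == tf_unit[j]]
    gene_table$gene_id[gene_table$gene_id == old] <- unname(tf_genes)[j]
    units$gene_id[units$gene_id == old] <- unname(tf_genes)[j]
  }

  list(genome = genome, enhancers = enh, truth = truth, pwms = pwms,
       thresholds = thresholds, tf_table = tf_table, motif2tf = motif2tf,
       gene_table = gene_table, units = units)
}

# Relative per-bin Poisson rates for one (mark, stage, lineage) condition;
# fractional bin-enhancer overlap scales the enrichment contribution.
chip_rates <- function(cfg, truth, mark, stage, lineage) {
  chroms <- unique(truth$chrom)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  nbin <- ceiling(cfg$chrom_len / cfg$bin_size)
  lam <- lapply(stats::setNames(chroms, chroms),
                function(ch) rep(1, nbin))
  state <- truth[[paste0(lineage, "_", stage)]]
  marked <- if (mark == "H3K4me1") state %in% c("primed", "active")
            else state %in% c("active", "acetyl_only")
  fold <- if (mark == "H3K4me1") cfg$enrichment_fold_primed
          else cfg$enrichment_fold_active
  idx <- which(marked)
  bs <- cfg$bin_size
  for (i in idx) {
    s0 <- truth$start[i] - 1
    e0 <- truth$end[i]
    b0 <- floor(s0 / bs)
    b1 <- ceiling(e0 / bs) - 1
    bins <- b0:b1
    w <- (pmin((bins + 1) * bs, e0) - pmax(bins * bs, s0)) / bs
    ch <- truth$chrom[i]
    lam[[ch]][bins + 1] <- lam[[ch]][bins + 1] + (fold - 1) * w
  }
  lam
}

scale_rates <- function(lam, depth) {
  tot <- sum(vapply(lam, sum, numeric(1)))
  lapply(lam, function(x) x * depth / tot)
}

#' Simulate one ChIP track (and optionally the matched input)
#'
#' Per-bin counts are Poisson around a flat background rate, with bins
#' inside enhancers whose truth state implies the mark (H3K4me1 for primed
#' and active, H3K27ac for active and acetyl-only) raised by the
#' configured fold; rates are scaled so the expected library size equals
#' `chip_depth`.  Deterministic given the config seed.
#'
#' @param cfg a `sim_config`.
#' @param truth truth table from [plant_enhancers()].
#' @param mark `"H3K4me1"` or `"H3K27ac"`.
#' @param stage stage name matching the lineage's stage set.
#' @param lineage `"astro"` or `"neuro"`.
#' @return a `BinnedTrack`.
#' @export
simulate_chip <- function(cfg, truth, mark, stage, lineage) {
  lam <- scale_rates(chip_rates(cfg, truth, mark, stage, lineage),
                     cfg$chip_depth)
  counts <- with_substream(cfg$seed, paste("chip", mark, stage, lineage),
                           lapply(lam, function(x) stats::rpois(length(x), x)))
  binned_track(counts, cfg$bin_size, paste(mark, stage, sep = "/"))
}

#' Simulate the genomic input track
#' @inheritParams simulate_chip
#' @export
simulate_input <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  nbin <- ceiling(cfg$chrom_len / cfg$bin_size)
  rate <- cfg$chip_depth / (nbin * cfg$n_chroms)
  counts <- with_substream(cfg$seed, "input",
                           lapply(stats::setNames(chroms, chroms),
                                  function(ch) stats::rpois(nbin, rate)))
  binned_track(counts, cfg$bin_size, "input")
}

# Per-gene expected expression multiplier across the seven conditions
# (ESC + three astro + three neuro stages).
expression_model <- function(cfg, planted) {
  conds <- c("ESC", stages_astro(), stages_neuro())
  genes <- planted$gene_table$gene_id
  n <- length(genes)
  mult <- matrix(1, n, length(conds), dimnames = list(genes, conds))

  # kinetic archetypes for genes without a linked enhancer (TF genes get
  # their own stage-matched profiles below)
  archetypes <- rbind(
    esc        = c(4, 1, 1, 1),
    esc_npc    = c(3, 3, 1, 1),
    npc_early  = c(1, 3, 3, 1),
    early      = c(1, 1, 4, 1),
    late       = c(1, 1, 1, 4)
  )
  linked <- stats::na.omit(planted$truth$linked_gene)
  tf_genes <- planted$motif2tf$gene
  free <- setdiff(genes, c(linked, tf_genes))
  arch <- with_substream(cfg$seed, "archetypes",
                         sample(rownames(archetypes), length(free),
                                replace = TRUE))
  astro_cols <- c("ESC", stages_astro())
  mult[free, astro_cols] <- archetypes[arch, ]
  mult[free, "nNPC"] <- mult[free, "aNPC"]

  # enhancer-coupled boost at stages where the linked enhancer is active
  tr <- planted$truth[!is.na(planted$truth$linked_gene), ]
  for (lin in c("astro", "neuro")) {
    stages <- if (lin == "astro") stages_astro() else stages_neuro()
    for (s in stages) {
      on <- tr$linked_gene[tr[[paste0(lin, "_", s)]] == "active"]
      mult[on, s] <- mult[on, s] * cfg$expr_boost
    }
  }

  # TF genes expressed around their stage
  tf_stage <- c(Tfa = "eA", Tfb = "eA", Tfc = "lA", Tfd = "aNPC",
                Tfe = "nNPC", Tff = "eN", Tfg = "lN")
  for (g in names(tf_stage)) {
    if (g %in% genes) mult[g, tf_stage[[g]]] <- 3
  }
  mult
}

#' Simulate the expression count matrix across stages and lineages
#'
#' Negative-binomial counts for every gene in `n_reps` replicates of the
#' shared embryonic stem cell stage and each of the six lineage stages.
#' Baselines are log-normal; genes linked to an enhancer are boosted
#' `expr_boost`-fold at stages where the enhancer is active in that
#' lineage; per-sample depth jitters by `size_factor_jitter`.
#'
#' @param cfg a `sim_config`.
#' @param planted output of [plant_enhancers()].
#' @return list: `counts` (gene x sample), `design` (sample, stage,
#'   lineage, replicate, condition), `mu` (expected gene x condition
#'   means), `baseline`.
#' @export
simulate_expression <- function(cfg, planted) {
  genes <- planted$gene_table$gene_id
  n <- length(genes)
  baseline <- with_substream(cfg$seed, "expression_baseline",
                             exp(stats::rnorm(n, cfg$baseline_log_mean,
                                              cfg$baseline_log_sd)))
  names(baseline) <- genes
  mult <- expression_model(cfg, planted)
  mu <- baseline * mult
  conds <- colnames(mult)
  samples <- paste(rep(conds, each = cfg$n_reps),
                   rep(seq_len(cfg$n_reps), length(conds)), sep = "_")
  design <- data.frame(
    sample = samples,
    stage = rep(conds, each = cfg$n_reps),
    lineage = rep(ifelse(conds == "ESC", "shared",
                         ifelse(conds %in% stages_astro(), "astro",
                                "neuro")), each = cfg$n_reps),
    replicate = rep(seq_len(cfg$n_reps), length(conds)),
    condition = "differentiation",
    stringsAsFactors = FALSE
  )
  counts <- with_substream(cfg$seed, "expression_counts", {
    sf <- stats::runif(length(samples), 1 - cfg$size_factor_jitter,
                       1 + cfg$size_factor_jitter)
    m <- sapply(seq_along(samples), function(j) {
      stats::rnbinom(n, mu = mu[, design$stage[j]] * sf[j],
                     size = 1 / cfg$nb_dispersion)
    })
    dimnames(m) <- list(genes, samples)
    m
  })
  list(counts = counts, design = design, mu = mu, baseline = baseline)
}

#' Simulate a TF knockdown experiment
#'
#' For a chromatin-remodeling TF the knockdown H3K27ac rate at the TF's
#' motif-bearing target enhancers is scaled by `kd_effect` and the target
#' genes' expression by `1 / expr_boost`; for a non-remodeling TF only the
#' target-gene expression changes.  The control arm is re-simulated from a
#' fresh seed substream.
#'
#' @param cfg a `sim_config`.
#' @param planted output of [plant_enhancers()].
#' @param tf_gene TF gene symbol (row of `planted$tf_table`).
#' @return list: `tf`, `stage`, `remodeling`, `control_track`, `kd_track`
#'   (H3K27ac `BinnedTrack`s), `counts` (gene x 2*n_reps), `design`,
#'   `target_enhancers`, `target_genes`.
#' @export
simulate_knockdown <- function(cfg, planted, tf_gene) {
  tfr <- planted$tf_table[planted$tf_table$tf_gene == tf_gene, ]
  if (nrow(tfr) != 1) stop("unknown TF: ", tf_gene)
  stage <- tfr$stage
  truth <- planted$truth
  has_motif <- vapply(strsplit(truth$motifs, ","), function(m)
    tfr$motif_id %in% m, logical(1))
  targets <- truth[has_motif, ]
  target_genes <- stats::na.omit(unique(targets$linked_gene))

  lam <- chip_rates(cfg, truth, "H3K27ac", stage, "astro")
  lam_kd <- lam
  if (tfr$remodeling) {
    # every bin touched by a target enhancer is scaled wholesale, so the
    # expected count ratio over any union of those bins is exactly kd_effect
    bs <- cfg$bin_size
    for (i in seq_len(nrow(targets))) {
      s0 <- targets$start[i] - 1
      e0 <- targets$end[i]
      bins <- floor(s0 / bs):(ceiling(e0 / bs) - 1)
      ch <- targets$chrom[i]
      lam_kd[[ch]][bins + 1] <- lam_kd[[ch]][bins + 1] * cfg$kd_effect
    }
  }
  ctrl_track <- binned_track(
    with_substream(cfg$seed, paste("kd_control_chip", tf_gene),
                   lapply(scale_rates(lam, cfg$chip_depth),
                          function(x) stats::rpois(length(x), x))),
    cfg$bin_size, paste0("H3K27ac/", stage, "/control"))
  kd_track <- binned_track(
    with_substream(cfg$seed, paste("kd_chip", tf_gene),
                   lapply(scale_rates(lam_kd, cfg$chip_depth),
                          function(x) stats::rpois(length(x), x))),
    cfg$bin_size, paste0("H3K27ac/", stage, "/si", tf_gene))

  baseline <- with_substream(cfg$seed, "expression_baseline",
                             exp(stats::rnorm(nrow(planted$gene_table),
                                              cfg$baseline_log_mean,
                                              cfg$baseline_log_sd)))
  names(baseline) <- planted$gene_table$gene_id
  mult <- expression_model(cfg, planted)
  mu_ctrl <- baseline * mult[, stage]
  mu_kd <- mu_ctrl
  mu_kd[target_genes] <- mu_kd[target_genes] * cfg$kd_expr_effect
  samples <- c(paste0("control_", seq_len(cfg$n_reps)),
               paste0("kd_", seq_len(cfg$n_reps)))
  counts <- with_substream(cfg$seed, paste("kd_counts", tf_gene), {
    sf <- stats::runif(length(samples), 1 - cfg$size_factor_jitter,
                       1 + cfg$size_factor_jitter)
    m <- sapply(seq_along(samples), function(j) {
      mu <- if (j <= cfg$n_reps) mu_ctrl else mu_kd
      stats::rnbinom(length(mu), mu = mu * sf[j],
                     size = 1 / cfg$nb_dispersion)
    })
    dimnames(m) <- list(names(mu_ctrl), samples)
    m
  })
  design <- data.frame(sample = samples, stage = stage, lineage = "astro",
                       replicate = rep(seq_len(cfg$n_reps), 2),
                       condition = rep(c("control", paste0("si", tf_gene)),
                                       each = cfg$n_reps),
                       stringsAsFactors = FALSE)
  list(tf = tf_gene, stage = stage, remodeling = tfr$remodeling,
       control_track = ctrl_track, kd_track = kd_track, counts = counts,
       design = design,
       target_enhancers = targets$enh_id, target_genes = target_genes)
}

#' Simulate the complete dataset
#'
#' Genome, gene models, planted enhancers/motifs, all twelve ChIP tracks
#' (two marks by six stages), the genomic input, the expression matrix and
#' the three knockdown experiments, all from one root seed.
#'
#' @param cfg a `sim_config`.
#' @return list bundling every component plus the truth tables.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  sim <- simulate_genome(cfg)
  planted <- plant_enhancers(cfg, sim)
  chip <- list()
  for (mark in c("H3K4me1", "H3K27ac")) {
    for (s in stages_astro()) {
      chip[[paste(mark, s, sep = "/")]] <-
        simulate_chip(cfg, planted$truth, mark, s, "astro")
    }
    for (s in stages_neuro()) {
      chip[[paste(mark, s, sep = "/")]] <-
        simulate_chip(cfg, planted$truth, mark, s, "neuro")
    }
  }
  input <- simulate_input(cfg)
  expr <- simulate_expression(cfg, planted)
  kds <- lapply(planted$tf_table$tf_gene, function(g)
    simulate_knockdown(cfg, planted, g))
  names(kds) <- planted$tf_table$tf_gene
  ann <- genome_annotation(planted$gene_table)
  list(cfg = cfg, genome = planted$genome, gene_table = planted$gene_table,
       annotation = ann, enhancers = planted$enhancers,
       truth = planted$truth, pwms = planted$pwms,
       thresholds = planted$thresholds, tf_table = planted$tf_table,
       motif2tf = planted$motif2tf, chip = chip, input = input,
       expression = expr, knockdowns = kds)
}
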