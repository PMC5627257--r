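test_that("generator is deterministic and seed-sensitive", {
  cfg <- tiny_config(seed = 1)
  ref1 <- sim_reference(cfg)
  ref2 <- sim_reference(cfg)
  expect_identical(serialize(ref1, NULL), serialize(ref2, NULL))

  t1 <- plant_truth(ref1, cfg)
  t2 <- plant_truth(ref2, cfg)
  expect_identical(serialize(t1, NULL), serialize(t2, NULL))

  r1 <- simulate_reads(ref1, t1, cfg, "s", "control", seed = 5)
  r2 <- simulate_reads(ref1, t1, cfg, "s", "control", seed = 5)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))

  ref_b <- sim_reference(tiny_config(seed = 2))
  tb <- plant_truth(ref_b, tiny_config(seed = 2))
  expect_false(identical(t1$het_snps$pos, tb$het_snps$pos))
})

test_that("reference bundle honours its invariants", {
  cfg <- tiny_config(seed = 3)
  ref <- sim_reference(cfg)
  for (df in list(ref$cpg_islands, ref$genes, ref$gaps, ref$asm_segments)) {
    expect_true(all(df$start >= 0))
    expect_true(all(df$end <= ref$chrom_lengths[df$chrom]))
    expect_true(all(df$end > df$start))
  }
  # gaps never overlap genes
  expect_false(any_overlap(ref$gaps, ref$genes))
  # at least one island per 100 kb, one gap per chromosome, one imprinted gene
  expect_gte(nrow(ref$cpg_islands), sum(ref$chrom_lengths) / 1e5)
  expect_true(all(table(ref$gaps$chrom) >= 1))
  expect_gte(nrow(ref$imprinted_genes), 1)

  # islands are CpG-enriched relative to background
  obs_exp <- function(ch, st, en) {
    s <- substr(ref$sequences[[ch]], st + 1, en)
    nC <- nchar(gsub("[^C]", "", s)); nG <- nchar(gsub("[^G]", "", s))
    n <- nchar(s)
    m <- gregexpr("CG", s, fixed = TRUE)[[1]]
    ncg <- if (m[1] == -1) 0 else length(m)
    ncg * n / max(1, nC * nG)
  }
  isl <- ref$cpg_islands[1, ]
  bg <- obs_exp(isl$chrom, 0, isl$start)   # everything before the island
  expect_gt(obs_exp(isl$chrom, isl$start, isl$end), bg)
})

test_that("a gene-free reference is valid for methylome-only runs", {
  cfg <- tiny_config(seed = 4, n_genes = 0L)
  ref <- sim_reference(cfg)
  expect_equal(nrow(ref$genes), 0)
  truth <- plant_truth(ref, cfg)
  expect_equal(nrow(truth$deg_truth), 0)
  rs <- simulate_reads(ref, truth, cfg, "s", "control", seed = 1)
  expect_gt(nrow(rs$reads), 0)
})

test_that("an over-stuffed chromosome raises a configuration error", {
  cfg <- tiny_config(seed = 1)
  cfg$chrom_lengths <- c(chrA = 20000L, chrB = 20000L)
  cfg$n_nonimprinted_regions <- 30L
  expect_error(sim_reference(cfg), "configuration error")
})

test_that("planted truth matches the requested design", {
  cfg <- study_config(seed = 11)
  ref <- sim_reference(cfg)
  truth <- plant_truth(ref, cfg)

  expect_equal(sum(truth$asm_regions$class == "imprinted"),
               cfg$n_imprinted_regions)
  expect_equal(sum(truth$asm_regions$class == "non_imprinted"),
               cfg$n_nonimprinted_regions)
  # regions do not overlap each other
  gr <- GenomicRanges::GRanges(
    truth$asm_regions$chrom,
    IRanges::IRanges(truth$asm_regions$start + 1, truth$asm_regions$end))
  expect_equal(sum(GenomicRanges::countOverlaps(gr, gr) > 1), 0)
  # SNP positions unique per chromosome
  expect_false(any(duplicated(truth$het_snps[c("chrom", "pos")])))
  # both alleles average 0.5 inside every region
  expect_equal(truth$asm_regions$mu_pat + truth$asm_regions$mu_mat,
               rep(1, nrow(truth$asm_regions)))
  # every coupled DEG has a DMR within the coupling distance in each sample
  coupled <- truth$deg_truth[truth$deg_truth$coupled, ]
  for (s in unique(truth$dmrs$sample_id)) {
    dmr_s <- truth$dmrs[truth$dmrs$sample_id == s, ]
    for (i in seq_len(nrow(coupled)))
      expect_true(any(dmr_s$chrom == coupled$chrom[i] &
                        dmr_s$start < coupled$end[i] + cfg$coupling_distance &
                        dmr_s$end > coupled$start[i] - cfg$coupling_distance))
  }
})

test_that("planted imprinted differences average the configured 0.73", {
  # average the generator's own draws over many regions
  diffs <- unlist(lapply(1:6, function(s) {
    cfg <- study_config(seed = 400 + s)
    truth <- plant_truth(sim_reference(cfg), cfg)
    truth$asm_regions$abs_diff[truth$asm_regions$class == "imprinted"]
  }))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 0.73), 3 * se + 0.01)
})

test_that("coupling_fraction = 0 plants no DEG-DMR coupling", {
  cfg <- tiny_config(seed = 5, coupling_fraction = 0)
  truth <- plant_truth(sim_reference(cfg), cfg)
  expect_false(any(truth$deg_truth$coupled))
  expect_true(all(is.na(truth$dmrs$coupled_gene)))
})

test_that("read calls follow the planted methylation probabilities", {
  # mu = 1 everywhere, no conversion failure, no M-bias -> all calls "C"
  cfg <- tiny_config(seed = 6, conversion_failure = 0, mbias_prob = 0,
                     spike_in_fraction = 0)
  ref <- sim_reference(cfg)
  truth <- plant_truth(ref, cfg)
  truth$background_meth <- lapply(truth$background_meth, function(x) x * 0 + 1)
  truth$asm_regions <- truth$asm_regions[0, ]
  rs <- simulate_reads(ref, truth, cfg, "s", "control", seed = 2)
  expect_true(all(rs$cpg_calls$call == "C"))

  # mu = 0 with conversion failure -> "C" fraction ~ failure rate
  cfg2 <- tiny_config(seed = 6, conversion_failure = 0.0069, mbias_prob = 0,
                      spike_in_fraction = 0)
  truth$background_meth <- lapply(truth$background_meth, function(x) x * 0)
  rs2 <- simulate_reads(ref, truth, cfg2, "s", "control", seed = 3)
  n <- nrow(rs2$cpg_calls)
  phat <- mean(rs2$cpg_calls$call == "C")
  expect_lt(abs(phat - 0.0069), 3 * sqrt(0.0069 * (1 - 0.0069) / n))
})

test_that("spike-in reads yield the configured conversion-rate estimate", {
  cfg <- tiny_config(seed = 7, conversion_failure = 0.005,
                     spike_in_fraction = 0.05, mbias_prob = 0)
  ref <- sim_reference(cfg)
  truth <- plant_truth(ref, cfg)
  rs <- trim_reads(simulate_reads(ref, truth, cfg, "s", "control", seed = 4))
  est <- estimate_conversion_rate(rs)
  n <- sum(rs$cpg_calls$chrom == "lambda")
  expect_lt(abs(est - 0.995), 3 * sqrt(0.005 * 0.995 / n))
})

test_that("allele-of-origin is latent: observation channel carries no label", {
  cfg <- tiny_config(seed = 8)
  ref <- sim_reference(cfg); truth <- plant_truth(ref, cfg)
  rs <- simulate_reads(ref, truth, cfg, "s", "control", seed = 5)
  expect_false("allele" %in% names(rs$reads))
  expect_false("allele" %in% names(rs$cpg_calls))
  expect_true(all(c("read_id", "allele") %in% names(rs$allele_truth)))
  # conservation: paternal + maternal calls = all calls at every CpG
  x <- merge(rs$cpg_calls, rs$allele_truth, by = "read_id")
  x <- x[x$chrom != "lambda", ]
  expect_true(all(x$allele %in% c("pat", "mat")))
})

test_that("expression table reflects fold-change truth and determinism", {
  cfg <- tiny_config(seed = 9, nb_size = 50, expr_zero_fraction = 0)
  ref <- sim_reference(cfg)
  truth <- plant_truth(ref, cfg)

  # null fold changes -> case and control means agree within NB noise
  truth0 <- truth
  truth0$deg_truth$log2_fold_change <- 0
  e0 <- emit_expression(truth0, ref, cfg, seed = 10)
  ctl <- rowMeans(e0[, grepl("^control", colnames(e0))])
  cas <- rowMeans(e0[, grepl("^case", colnames(e0))])
  big <- ctl > 50
  expect_lt(median(abs(log2((cas[big] + 1) / (ctl[big] + 1)))), 0.5)

  # one strong DEG -> case mean ~ 4x control mean
  truth1 <- truth0
  truth1$deg_truth$log2_fold_change[1] <- 2
  set.seed(42)
  reps <- replicate(40, {
    e <- emit_expression(truth1, ref, cfg, seed = sample.int(1e6, 1))
    mean(e[1, grepl("^case", colnames(e))]) /
      max(1, mean(e[1, grepl("^control", colnames(e))]))
  })
  expect_lt(abs(median(reps) - 4), 1)

  # fixed seed -> identical table
  expect_identical(emit_expression(truth, ref, cfg, seed = 3),
                   emit_expression(truth, ref, cfg, seed = 3))
})

test_that("control methylome is bimodal with hypomethylated islands", {
  cfg <- study_config(seed = 12)
  ref <- sim_reference(cfg); truth <- plant_truth(ref, cfg)
  rs <- trim_reads(simulate_reads(ref, truth, cfg, "control_1", "control",
                                  seed = 113))
  tab <- coverage_filter(pileup_cpgs(rs, ref, snps = truth$het_snps), 5)
  s <- methylation_summary(tab, ref$cpg_islands)
  expect_true(s$bimodal)
  expect_lt(s$island_mean, s$non_island_mean)
})
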