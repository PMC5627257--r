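mk_deg <- function(id, chrom, start, end)
  data.frame(gene_id = id, chrom = chrom, start = start, end = end)

test_that("association is overlap with the extended gene interval", {
  degs <- mk_deg("g1", "chr1", 100000L, 103000L)
  # DMR 3 kb upstream -> associated at 5 kb extension
  dmr_near <- data.frame(chrom = "chr1", start = 96000L, end = 97000L)
  expect_equal(associate(degs, dmr_near, 5000), "g1")
  # DMR 12 kb away: not at 5 kb, associated at 20 kb
  dmr_far <- data.frame(chrom = "chr1", start = 115000L, end = 116000L)
  expect_equal(associate(degs, dmr_far, 5000), character(0))
  expect_equal(associate(degs, dmr_far, 20000), "g1")
  # unknown chromosome skipped with a warning
  expect_warning(out <- associate(degs, data.frame(chrom = "chrX",
                                                   start = 1L, end = 10L),
                                  5000), "unknown")
  expect_equal(out, character(0))
})

test_that("association equals an exhaustive pairwise check on a toy set", {
  set.seed(12)
  degs <- mk_deg(sprintf("g%02d", 1:10),
                 sample(c("chr1", "chr2"), 10, TRUE),
                 st <- sample.int(900000L, 10), st + 3000L)
  dmrs <- data.frame(chrom = sample(c("chr1", "chr2"), 4, TRUE),
                     start = ds <- sample.int(900000L, 4), end = ds + 1500L)
  for (ext in c(0, 5000, 20000))
    expect_equal(sort(associate(degs, dmrs, ext)),
                 brute_associated(degs, dmrs, ext))
})

test_that("linkage fraction is the associated percentage", {
  degs <- mk_deg(sprintf("g%03d", 1:200), "chr1",
                 seq(0L, by = 20000L, length.out = 200),
                 seq(0L, by = 20000L, length.out = 200) + 2000L)
  # DMRs right next to the first three genes -> 1.5%
  dmrs <- data.frame(chrom = "chr1", start = degs$start[1:3] + 2500L,
                     end = degs$start[1:3] + 3500L)
  expect_equal(deg_dmr_linkage_fraction(degs, dmrs, 5000), 1.5)
  expect_equal(deg_dmr_linkage_fraction(degs, dmrs[0, ], 5000), 0)
})

test_that("shuffling preserves chromosome and length, and avoids gaps", {
  set.seed(5)
  dmrs <- data.frame(chrom = rep(c("chr1", "chr2"), c(30, 20)),
                     start = st <- sample.int(800000L, 50),
                     end = st + sample(c(500L, 1500L, 4000L), 50, TRUE))
  lens <- c(chr1 = 1000000L, chr2 = 900000L)
  gaps <- data.frame(chrom = c("chr1", "chr2"),
                     start = c(200000L, 400000L), end = c(260000L, 460000L))
  sh <- shuffle_dmrs(dmrs, lens, gaps, seed = 8, n_reps = 20)
  expect_equal(nrow(sh), 20 * 50)
  expect_identical(sh$chrom, rep(dmrs$chrom, 20))
  expect_identical(sh$end - sh$start, rep(dmrs$end - dmrs$start, 20))
  expect_true(all(sh$start >= 0 & sh$end <= lens[sh$chrom]))
  expect_false(any_overlap(sh, gaps))
  # determinism
  expect_identical(sh, shuffle_dmrs(dmrs, lens, gaps, seed = 8, n_reps = 20))
})

test_that("gap-free placement is uniform along the chromosome", {
  dmr <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
  lens <- c(chr1 = 1000000L)
  sh <- shuffle_dmrs(dmr, lens, gaps = NULL, seed = 10, n_reps = 10000)
  mid <- (sh$start + sh$end) / 2
  se <- (lens / sqrt(12)) / sqrt(10000)
  expect_lt(abs(mean(mid) - lens / 2), 3 * se)
})

test_that("placement respects a gap covering most of the chromosome", {
  dmr <- data.frame(chrom = "chr1", start = 0L, end = 500L)
  lens <- c(chr1 = 100000L)
  gap <- data.frame(chrom = "chr1", start = 0L, end = 90000L)
  sh <- shuffle_dmrs(dmr, lens, gap, seed = 2, n_reps = 500)
  expect_true(all(sh$start >= 90000L))
  # an impossible interval raises a placement error
  wide <- data.frame(chrom = "chr1", start = 0L, end = 20000L)
  expect_error(shuffle_dmrs(wide, lens, gap, seed = 2, max_tries = 200),
               "placement error")
})

test_that("the two-cell chi-square matches its closed form", {
  r <- association_chisq(30, 12, 2000)
  expect_equal(r$chi2, 324 / 12 + 324 / 1988, tolerance = 1e-12)
  expect_equal(r$p_value, pchisq(324 / 12 + 324 / 1988, 1,
                                 lower.tail = FALSE))
  expect_lt(abs(r$chi2 - 27.16), 0.01)
  expect_lt(abs(r$p_value - 1.9e-7), 2e-8)
  # O = E -> no signal
  r0 <- association_chisq(12, 12, 2000)
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p_value, 1)
  # degenerate expectation
  expect_true(is.na(association_chisq(3, 0, 10)$chi2))
})

test_that("permutation expectation is deterministic and coherent", {
  cfg <- assoc_config(seed = 3)
  ref <- sim_reference(cfg); truth <- plant_truth(ref, cfg)
  degs <- truth$deg_truth[truth$deg_truth$is_deg, ]
  dmrs <- truth$dmrs[truth$dmrs$sample_id == "case_1", ]
  r1 <- permutation_expectation(degs, dmrs, ref$chrom_lengths, ref$gaps,
                                extension = 5000, n_shuffles = 200, seed = 4)
  r2 <- permutation_expectation(degs, dmrs, ref$chrom_lengths, ref$gaps,
                                extension = 5000, n_shuffles = 200, seed = 4)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
  expect_equal(r1$n_observed,
               length(associate(degs, dmrs, 5000,
                                chroms = names(ref$chrom_lengths))))
  expect_true(r1$n_expected >= 0 && r1$n_expected <= r1$n_deg_total)
})

test_that("association is monotone in the extension distance", {
  for (s in 1:3) {
    cfg <- assoc_config(seed = 40 + s)
    ref <- sim_reference(cfg); truth <- plant_truth(ref, cfg)
    degs <- truth$deg_truth[truth$deg_truth$is_deg, ]
    dmrs <- truth$dmrs[truth$dmrs$sample_id == "case_1", ]
    a5 <- associate(degs, dmrs, 5000)
    a20 <- associate(degs, dmrs, 20000)
    expect_true(all(a5 %in% a20))
  }
})

test_that("dmr_overlap returns exact pairwise intersections", {
  a <- data.frame(chrom = "chr1", start = c(0L, 100L, 500L),
                  end = c(50L, 200L, 600L))
  expect_equal(nrow(dmr_overlap(a, a)), 3)   # identical sets all overlap
  b <- data.frame(chrom = "chr1", start = c(1000L, 2000L),
                  end = c(1100L, 2100L))
  expect_equal(nrow(dmr_overlap(a, b)), 0)   # disjoint
  # toy 5 vs 5 equals brute force
  set.seed(31)
  x <- data.frame(chrom = "chr1", start = sx <- sample.int(5000L, 5),
                  end = sx + 400L)
  y <- data.frame(chrom = "chr1", start = sy <- sample.int(5000L, 5),
                  end = sy + 400L)
  got <- dmr_overlap(x, y)
  brute <- do.call(rbind, lapply(1:5, function(i) {
    hits <- which(y$start < x$end[i] & y$end > x$start[i])
    if (!length(hits)) return(NULL)
    data.frame(start = pmax(x$start[i], y$start[hits]),
               end = pmin(x$end[i], y$end[hits]))
  }))
  expect_equal(nrow(got), NROW(brute))
  if (NROW(brute))
    expect_setequal(paste(got$start, got$end), paste(brute$start, brute$end))
})

test_that("TSS-window differences are strand-aware means over covered CpGs", {
  degs <- data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                     strand = c("+", "-"), tss = c(10000L, 30000L),
                     log2_fold_change = c(2, -2))
  # case uniformly 0.8, control 0.3 inside the plus-strand gene's window
  pos_p <- seq(8600L, 10400L, by = 100L)
  pos_m <- seq(29600L, 31400L, by = 100L)
  mk <- function(lv) data.frame(chrom = "chr1", pos = c(pos_p, pos_m),
                                n_C = as.integer(lv * 10), n_T = as.integer(10 - lv * 10))
  d <- tss_window_meth_diff(degs, mk(0.8), mk(0.3))
  expect_equal(d$delta, c(0.5, 0.5), tolerance = 1e-12)

  # minus-strand window extends to the right of the TSS in genome space:
  # a CpG 1 kb right of the minus TSS is inside, 1 kb left is outside
  one <- data.frame(gene_id = "gm", chrom = "chr1", strand = "-",
                    tss = 30000L, log2_fold_change = 2)
  inside <- data.frame(chrom = "chr1", pos = 31000L, n_C = 8L, n_T = 2L)
  outside <- data.frame(chrom = "chr1", pos = 28900L, n_C = 8L, n_T = 2L)
  expect_false(is.na(tss_window_meth_diff(one, inside, inside)$delta))
  expect_true(is.na(tss_window_meth_diff(one, outside, outside)$delta))

  # only genes at >= 2-fold change are reported
  weak <- data.frame(gene_id = "gw", chrom = "chr1", strand = "+",
                     tss = 10000L, log2_fold_change = 0.5)
  expect_equal(nrow(tss_window_meth_diff(rbind(degs, weak), mk(0.8), mk(0.3))),
               2)
})

test_that("pooled t test reproduces textbook and degenerate cases", {
  bw <- pooled_t_test(405, 10, 4, 592, 95, 4)
  expect_equal(unname(bw$parameter), 6)
  expect_lt(abs(unname(bw$statistic) + 3.914), 0.01)
  expect_equal(round(bw$p.value, 3), 0.008)

  expect_equal(pooled_t_test(5, 1, 4, 5, 1, 4)$p.value, 1)
  expect_equal(pooled_t_test(5, 0, 4, 5, 0, 4)$p.value, 1)
  expect_warning(d <- pooled_t_test(5, 0, 4, 6, 0, 4), "degenerate")
  expect_equal(d$p.value, 0)

  # agrees with t.test(var.equal = TRUE) on raw data
  set.seed(88)
  for (i in 1:20) {
    x <- rnorm(6, 0, 1); y <- rnorm(8, 1, 2)
    ours <- pooled_t_test(mean(x), sd(x), 6, mean(y), sd(y), 8)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
    expect_equal(unname(ours$statistic), unname(ref$statistic),
                 tolerance = 1e-10)
  }
})

test_that("the naive window scanner finds a planted block difference", {
  pos <- seq(0L, 49999L, by = 50L)
  lv_case <- ifelse(pos >= 20000L & pos < 22000L, 0.9, 0.5)
  case <- data.frame(chrom = "chr1", pos = pos, level = lv_case)
  ctl <- data.frame(chrom = "chr1", pos = pos, level = 0.5)
  d <- scan_dmrs_naive(case, ctl)
  expect_equal(nrow(d), 1)
  expect_equal(d$start, 20000L)
  expect_equal(d$end, 22000L)
  expect_equal(d$mean_diff, 0.4, tolerance = 1e-12)
})
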