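mk_snps <- function(chrom = "chrA", pos, pat, mat, sire = NULL) {
  if (is.null(sire)) sire <- paste(pat, pat, sep = "/")
  data.frame(chrom = chrom, pos = pos, pat_base = pat, mat_base = mat,
             sire_genotype = sire)
}

one_read <- function(strand, snp_pos, base, read_id = 1L) {
  manual_read_set(
    reads = data.frame(read_id = read_id, chrom = "chrA", start = 0L,
                       end = 100L, strand = strand, mate = 1L),
    snp_calls = data.frame(read_id = read_id, pos = snp_pos, base = base))
}

test_that("parental origin follows the sire-genotype voting rule", {
  # sire A/A (paternal A), dam allele G; read base A -> paternal
  snps <- mk_snps(pos = 50L, pat = "A", mat = "G")
  expect_equal(assign_parental_origin(one_read("+", 50L, "A"), snps)$origin,
               "pat")
  expect_equal(assign_parental_origin(one_read("+", 50L, "G"), snps)$origin,
               "mat")
  # base matching neither allele -> ambiguous
  expect_equal(assign_parental_origin(one_read("+", 50L, "T"), snps)$origin,
               "ambiguous")

  # conflicting votes across two SNPs -> ambiguous
  snps2 <- mk_snps(pos = c(20L, 60L), pat = c("A", "A"), mat = c("G", "G"))
  rs <- manual_read_set(
    reads = data.frame(read_id = 1L, chrom = "chrA", start = 0L, end = 100L,
                       strand = "+", mate = 1L),
    snp_calls = data.frame(read_id = c(1L, 1L), pos = c(20L, 60L),
                           base = c("A", "G")))
  expect_equal(assign_parental_origin(rs, snps2)$origin, "ambiguous")

  # heterozygous sire -> SNP uninformative
  snps3 <- mk_snps(pos = 50L, pat = "A", mat = "G", sire = "A/G")
  expect_equal(assign_parental_origin(one_read("+", 50L, "A"), snps3)$origin,
               "ambiguous")
})

test_that("bisulfite-confounded SNPs are skipped strand-specifically", {
  ct <- mk_snps(pos = 50L, pat = "C", mat = "T")
  # a plus-strand read cannot distinguish converted C from the T allele
  expect_equal(assign_parental_origin(one_read("+", 50L, "T"), ct)$origin,
               "ambiguous")
  # the same SNP read on the minus strand is informative
  expect_equal(assign_parental_origin(one_read("-", 50L, "T"), ct)$origin,
               "mat")
  ga <- mk_snps(pos = 50L, pat = "G", mat = "A")
  expect_equal(assign_parental_origin(one_read("-", 50L, "A"), ga)$origin,
               "ambiguous")
  expect_equal(assign_parental_origin(one_read("+", 50L, "A"), ga)$origin,
               "mat")
})

test_that("allelic pooling sums counts across samples and drops ambiguity", {
  ref <- manual_ref(list(chrA = c(500L)))
  snps <- mk_snps(pos = 450L, pat = "A", mat = "G")
  mk_sample <- function(calls, bases) {
    n <- length(calls)
    manual_read_set(
      reads = data.frame(read_id = seq_len(n), chrom = "chrA", start = 440L,
                         end = 540L, strand = "+", mate = 1L),
      cpg_calls = data.frame(read_id = seq_len(n), pos = 500L, call = calls),
      snp_calls = data.frame(read_id = seq_len(n), pos = 450L, base = bases))
  }
  # sample 1: paternal 2C/1T; sample 2: paternal 1C plus one ambiguous read
  s1 <- trim_reads(mk_sample(c("C", "C", "T"), c("A", "A", "A")))
  s2 <- trim_reads(mk_sample(c("C", "C"), c("A", "T")))
  a1 <- assign_parental_origin(s1, snps)
  a2 <- assign_parental_origin(s2, snps)
  tab <- pool_allelic_counts(list(s1, s2), list(a1, a2), ref, snps = snps)
  expect_equal(tab$pat_C, 3L)
  expect_equal(tab$pat_T, 1L)
  expect_equal(tab$mat_C + tab$mat_T, 0L)
})

test_that("the 4x-per-allele rule gates testing", {
  tab <- data.frame(chrom = "chrA", pos = c(100L, 200L),
                    pat_C = c(3L, 6L), pat_T = c(0L, 2L),
                    mat_C = c(2L, 1L), mat_T = c(8L, 7L))
  out <- asm_test_cpgs(tab, min_allele_cov = 4)
  expect_equal(out$tested, c(FALSE, TRUE))   # pat coverage 3 fails the rule
  expect_true(is.na(out$p_value[1]))
  expect_false(is.na(out$p_value[2]))
})

test_that("the Fisher ASM test matches exact enumeration on known tables", {
  expect_equal(fisher_asm_test(8, 0, 0, 8), 2 / choose(16, 8))
  expect_equal(fisher_asm_test(5, 5, 5, 5), 1)
  expect_equal(fisher_asm_test(4, 0, 0, 4), 2 / 70)
  # (4,0,0,4) is not a candidate at the 0.01 threshold
  tab <- data.frame(chrom = "c", pos = 1L, pat_C = 4L, pat_T = 0L,
                    mat_C = 0L, mat_T = 4L)
  expect_false(asm_test_cpgs(tab)$candidate)
  expect_error(fisher_asm_test(-1, 0, 0, 4), "non-negative")
})

test_that("the Fisher ASM test agrees with stats::fisher.test", {
  set.seed(99)
  for (i in 1:200) {
    x <- rpois(4, sample(c(2, 8, 20), 1))
    ours <- fisher_asm_test(x[1], x[2], x[3], x[4])
    ref_p <- stats::fisher.test(matrix(x, 2, byrow = TRUE))$p.value
    expect_equal(ours, ref_p, tolerance = 1e-8)
  }
})

test_that("the test is symmetric under allele-label swap", {
  set.seed(7)
  for (i in 1:50) {
    x <- rpois(4, 10)
    expect_equal(fisher_asm_test(x[1], x[2], x[3], x[4]),
                 fisher_asm_test(x[3], x[4], x[1], x[2]))
  }
})

test_that("permuting alleles preserves coverage and is seed-reproducible", {
  a <- data.frame(read_id = 1:100,
                  origin = sample(c("pat", "mat", "ambiguous"), 100, TRUE))
  p1 <- permute_alleles(a, seed = 3)
  p2 <- permute_alleles(a, seed = 3)
  expect_identical(p1, p2)
  expect_identical(p1$origin == "ambiguous", a$origin == "ambiguous")
  expect_equal(sum(p1$origin != "ambiguous"), sum(a$origin != "ambiguous"))
  p3 <- permute_alleles(a, seed = 4)
  expect_false(identical(p1$origin, p3$origin))
})

test_that("the permutation FDR is the randomized/observed candidate ratio", {
  expect_equal(round(estimate_fdr(109794, 5507), 4), 0.0502)
  expect_equal(estimate_fdr(100, 0), 0)
  expect_equal(estimate_fdr(100, 100), 1)
  expect_equal(estimate_fdr(100, c(10, 20)), 0.15)  # replicates averaged
  expect_warning(r <- estimate_fdr(0, 5), "undefined")
  expect_true(is.na(r))
})

test_that("candidate chaining yields hand-traceable regions", {
  tab <- data.frame(chrom = "chrA",
                    pos = c(100L, 150L, 200L, 900L, 950L, 1000L),
                    tested = TRUE, candidate = TRUE)
  r <- cluster_asm_regions(tab, max_gap = 250, min_cluster_size = 3,
                           min_purity = 0.5)
  expect_equal(nrow(r), 2)
  expect_equal(r$start, c(100L, 900L))
  expect_equal(r$end, c(202L, 1002L))
  expect_equal(r$n_candidate_cpgs, c(3L, 3L))

  # two isolated candidates never form a region at min_cluster_size = 5
  tab2 <- data.frame(chrom = "chrA", pos = c(100L, 5000L),
                     tested = TRUE, candidate = TRUE)
  expect_equal(nrow(cluster_asm_regions(tab2, min_cluster_size = 5)), 0)

  # purity: a dilute chain is rejected
  tab3 <- data.frame(chrom = "chrA", pos = seq(100L, 1400L, by = 100L),
                     tested = TRUE,
                     candidate = rep(c(TRUE, FALSE, FALSE), length.out = 14))
  expect_equal(nrow(cluster_asm_regions(tab3, max_gap = 400,
                                        min_cluster_size = 3,
                                        min_purity = 0.5, edge_gap = 400)), 0)

  # an isolated terminal candidate beyond edge_gap is trimmed off
  tab4 <- data.frame(chrom = "chrA",
                     pos = c(100L, 130L, 160L, 190L, 220L, 1100L),
                     tested = TRUE, candidate = TRUE)
  r4 <- cluster_asm_regions(tab4, max_gap = 1000, min_cluster_size = 5,
                            edge_gap = 250)
  expect_equal(nrow(r4), 1)
  expect_equal(r4$end, 222L)
  expect_equal(nrow(cluster_asm_regions(tab4[0, ])), 0)  # empty in, empty out
})

test_that("regions classify by distance to known imprinted genes", {
  regions <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                        start = c(10000L, 2100000L, 5000L),
                        end = c(11000L, 2101000L, 6000L))
  imp <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
  cl <- classify_regions(regions, imp)
  expect_equal(cl$class, c("imprinted", "non_imprinted", "non_imprinted"))
  # empty annotation -> everything non-imprinted; NULL -> unannotated
  expect_true(all(classify_regions(regions, imp[0, ])$class ==
                    "non_imprinted"))
  expect_true(all(classify_regions(regions, NULL)$class == "unannotated"))
})

test_that("region characterization reports allele means and differences", {
  regions <- data.frame(region_id = "asm_001", chrom = "chrA",
                        start = 100L, end = 300L, class = "non_imprinted")
  tab <- asm_test_cpgs(data.frame(
    chrom = "chrA", pos = c(150L, 250L),
    pat_C = c(9L, 9L), pat_T = c(1L, 1L),
    mat_C = c(1L, 1L), mat_T = c(9L, 9L)))
  ch <- characterize_regions(regions, tab)
  expect_equal(ch$pat_mean, 0.9)
  expect_equal(ch$mat_mean, 0.1)
  expect_equal(ch$abs_diff, 0.8)
  cs <- attr(ch, "class_summary")
  expect_equal(cs$mean_abs_diff[cs$class == "non_imprinted"], 0.8)
})
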