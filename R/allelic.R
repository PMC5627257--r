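#' Assign reads to their parental origin at heterozygous SNPs
#'
#' Every informative SNP a read overlaps casts one vote: the base matching
#' the sire's homozygous allele votes paternal, the other parental allele
#' votes maternal. SNPs where the sire is heterozygous are uninformative and
#' skipped, as are SNPs that bisulfite conversion confounds on the read's
#' strand: C/T alleles on a plus-strand read (an unmethylated C reads as T)
#' and G/A alleles on a minus-strand read. Reads with conflicting votes, or
#' with no informative vote, are `ambiguous`.
#'
#' @param rs a `read_set` (trim first; see [trim_reads()]).
#' @param het_snps data frame with `chrom`, `pos`, `pat_base`, `mat_base`,
#'   `sire_genotype` (`"X/Y"`; informative only when X == Y).
#' @return data frame `read_id`, `origin` (`"pat"`, `"mat"` or
#'   `"ambiguous"`) covering every read with at least one SNP call.
#' @export
assign_parental_origin <- function(rs, het_snps) {
  stopifnot(inherits(rs, "read_set"))
  sc <- rs$snp_calls
  empty <- data.frame(read_id = integer(0), origin = character(0))
  if (!nrow(sc) || !nrow(het_snps)) return(empty)

  snp <- data.table::as.data.table(
    het_snps[, c("chrom", "pos", "pat_base", "mat_base", "sire_genotype")])
  x <- snp[sc, on = c("chrom", "pos"), nomatch = NULL]
  if (!nrow(x)) return(empty)

  al <- data.table::tstrsplit(x$sire_genotype, "/", fixed = TRUE)
  sire_hom <- al[[1]] == al[[2]]
  pair_ct <- (x$pat_base == "C" & x$mat_base == "T") |
             (x$pat_base == "T" & x$mat_base == "C")
  pair_ga <- (x$pat_base == "G" & x$mat_base == "A") |
             (x$pat_base == "A" & x$mat_base == "G")
  confounded <- (x$strand == "+" & pair_ct) | (x$strand == "-" & pair_ga)
  x <- x[sire_hom & !confounded]
  if (!nrow(x)) {
    ids <- unique(sc$read_id)
    return(data.frame(read_id = ids, origin = "ambiguous"))
  }

  x[, vote := data.table::fifelse(base == pat_base, "pat",
               data.table::fifelse(base == mat_base, "mat", NA_character_))]
  votes <- x[!is.na(vote),
             list(n_pat = sum(vote == "pat"), n_mat = sum(vote == "mat")),
             by = read_id]
  votes[, origin := data.table::fifelse(n_pat > 0L & n_mat == 0L, "pat",
                     data.table::fifelse(n_mat > 0L & n_pat == 0L, "mat",
                                         "ambiguous"))]
  out <- merge(data.table::data.table(read_id = unique(sc$read_id)),
               votes[, list(read_id, origin)], by = "read_id", all.x = TRUE)
  out[is.na(origin), origin := "ambiguous"]
  data.table::setDF(out)
  out
}

#' Pool per-allele CpG counts across samples
#'
#' Sums, per CpG and parental allele, the C/T calls of all assigned reads
#' pooled over the given samples (conventionally the control group).
#' Ambiguous reads contribute nothing. The same CpG-context and
#' SNP-exclusion rules as [pileup_cpgs()] apply.
#'
#' @param read_sets list of trimmed `read_set` objects.
#' @param assignments list of matching [assign_parental_origin()] tables.
#' @param ref the `ref_bundle` (for CpG context).
#' @param snps SNP table used to exclude CpGs overlapping a SNP (typically
#'   the same het SNPs used for assignment).
#' @return data frame `chrom`, `pos`, `pat_C`, `pat_T`, `mat_C`, `mat_T`,
#'   sorted by position; one row per CpG with at least one allelic call.
#' @export
pool_allelic_counts <- function(read_sets, assignments, ref, snps = NULL) {
  stopifnot(length(read_sets) == length(assignments))
  pieces <- lapply(seq_along(read_sets), function(i) {
    rs <- read_sets[[i]]
    a <- data.table::as.data.table(assignments[[i]])
    calls <- rs$cpg_calls
    if (!nrow(calls) || !nrow(a)) return(NULL)
    x <- calls[a[origin != "ambiguous"], on = "read_id", nomatch = NULL]
    x[chrom != "lambda"]
  })
  calls <- data.table::rbindlist(pieces[!vapply(pieces, is.null, logical(1))])
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      pat_C = integer(0), pat_T = integer(0),
                      mat_C = integer(0), mat_T = integer(0))
  if (is.null(calls) || !nrow(calls)) return(empty)

  # same context filtering as the total pileup
  keep <- rep(TRUE, nrow(calls))
  for (ch in unique(calls$chrom)) {
    i <- which(calls$chrom == ch)
    sites <- ref$cpg_sites[[ch]]
    if (is.null(sites)) { keep[i] <- FALSE; next }
    hit <- findInterval(calls$pos[i], sites)
    keep[i] <- hit > 0L & sites[pmax(hit, 1L)] == calls$pos[i]
  }
  calls <- calls[keep]
  if (!is.null(snps) && nrow(snps)) {
    bad <- data.table::data.table(
      chrom = rep(snps$chrom, 2L),
      pos = c(as.integer(snps$pos), as.integer(snps$pos) - 1L))
    calls <- calls[!bad, on = c("chrom", "pos")]
  }
  if (!nrow(calls)) return(empty)

  tab <- calls[call %in% c("C", "T"),
               list(pat_C = sum(origin == "pat" & call == "C"),
                    pat_T = sum(origin == "pat" & call == "T"),
                    mat_C = sum(origin == "mat" & call == "C"),
                    mat_T = sum(origin == "mat" & call == "T")),
               by = list(chrom, pos)]
  data.table::setorder(tab, chrom, pos)
  data.table::setDF(tab)
  tab
}

#' Two-sided Fisher exact test for allele-specific methylation
#'
#' Exact two-sided p-value for the 2x2 table of per-allele C/T counts at one
#' CpG, computed from the hypergeometric distribution (all outcomes whose
#' probability does not exceed that of the observed table). Vectorized over
#' CpGs.
#'
#' @param pat_C,pat_T,mat_C,mat_T non-negative counts.
#' @return numeric vector of p-values.
#' @export
#' @examples
#' fisher_asm_test(8, 0, 0, 8)   # 2 / choose(16, 8)
#' fisher_asm_test(5, 5, 5, 5)   # 1
fisher_asm_test <- function(pat_C, pat_T, mat_C, mat_T) {
  n <- max(length(pat_C), length(pat_T), length(mat_C), length(mat_T))
  a <- rep_len(as.integer(pat_C), n); b <- rep_len(as.integer(pat_T), n)
  c_ <- rep_len(as.integer(mat_C), n); d <- rep_len(as.integer(mat_T), n)
  if (any(c(a, b, c_, d) < 0)) stop("counts must be non-negative")
  p <- numeric(n)
  for (i in seq_len(n)) {
    m <- a[i] + c_[i]            # total C
    nn <- b[i] + d[i]            # total T
    k <- a[i] + b[i]             # paternal coverage
    lo <- max(0L, k - nn); hi <- min(k, m)
    dens <- dhyper(lo:hi, m, nn, k)
    p[i] <- min(1, sum(dens[dens <= dens[a[i] - lo + 1L] * (1 + 1e-7)]))
  }
  p
}

#' Test pooled allelic counts for ASM candidates
#'
#' Applies the minimum per-allele coverage rule (default 4x on each allele),
#' the Fisher exact test, and the candidate threshold.
#'
#' @param allelic table from [pool_allelic_counts()].
#' @param min_allele_cov minimum coverage of each allele for a CpG to be
#'   tested (default 4).
#' @param alpha candidate p-value threshold (default 0.01).
#' @return the table with added `tested`, `p_value`, `pat_level`,
#'   `mat_level` and `candidate` columns (`p_value` NA when untested).
#' @export
asm_test_cpgs <- function(allelic, min_allele_cov = 4L, alpha = 0.01) {
  out <- allelic
  pat_cov <- out$pat_C + out$pat_T
  mat_cov <- out$mat_C + out$mat_T
  out$tested <- pmin(pat_cov, mat_cov) >= min_allele_cov
  out$p_value <- NA_real_
  if (any(out$tested))
    out$p_value[out$tested] <- fisher_asm_test(
      out$pat_C[out$tested], out$pat_T[out$tested],
      out$mat_C[out$tested], out$mat_T[out$tested])
  out$pat_level <- methylation_level(out$pat_C, out$pat_T)
  out$mat_level <- methylation_level(out$mat_C, out$mat_T)
  out$candidate <- out$tested & !is.na(out$p_value) & out$p_value < alpha
  out
}

#' Randomize allele labels for the permutation FDR
#'
#' Replaces the parental label of every assigned (non-ambiguous) read with a
#' fair coin flip, leaving ambiguous reads ambiguous. Rerunning the identical
#' pooling, coverage filter and test on the randomized labels yields the
#' null candidate count used by [estimate_fdr()]. Total allelic coverage at
#' every CpG is preserved.
#'
#' @param assignments list (or single data frame) of
#'   [assign_parental_origin()] tables.
#' @param seed integer seed for the coin flips.
#' @return object of the same shape with randomized `origin` labels.
#' @export
permute_alleles <- function(assignments, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  single <- is.data.frame(assignments)
  if (single) assignments <- list(assignments)
  out <- lapply(assignments, function(a) {
    lab <- a$origin != "ambiguous"
    a$origin[lab] <- sample(c("pat", "mat"), sum(lab), replace = TRUE)
    a
  })
  if (single) out[[1]] else out
}

#' Permutation estimate of the ASM false discovery rate
#'
#' The ratio of candidates found under randomized allele labels to observed
#' candidates; with several permutation replicates the randomized count is
#' averaged first.
#'
#' @param n_obs_candidates observed candidate count (> 0).
#' @param n_perm_candidates candidate count(s) from randomized datasets.
#' @return estimated FDR (a proportion).
#' @export
#' @examples
#' estimate_fdr(109794, 5507)   # ~0.05
estimate_fdr <- function(n_obs_candidates, n_perm_candidates) {
  if (length(n_obs_candidates) != 1L || is.na(n_obs_candidates))
    stop("n_obs_candidates must be a single count")
  if (n_obs_candidates <= 0) {
    warning("no observed candidates; FDR undefined")
    return(NA_real_)
  }
  mean(n_perm_candidates) / n_obs_candidates
}
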