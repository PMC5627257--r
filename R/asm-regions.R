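#' Cluster candidate ASM CpGs into regions
#'
#' Candidate CpGs on one chromosome separated by at most `max_gap` bp are
#' chained; a chain becomes a region when it holds at least
#' `min_cluster_size` candidates and the candidate fraction among tested
#' CpGs inside its span is at least `min_purity`. The region interval spans
#' the first to last candidate CpG, end-exclusive +2 for the dinucleotide.
#'
#' @param asm_table output of [asm_test_cpgs()] (needs `tested` and
#'   `candidate` columns).
#' @param max_gap maximum bp between consecutive chained candidates (default
#'   1000; candidates exist only near informative SNPs, so the chain must
#'   bridge SNP-poor stretches).
#' @param min_cluster_size minimum candidates per region.
#' @param min_purity minimum candidate/tested fraction within the span.
#' @param edge_gap terminal candidates whose gap to the rest of the chain
#'   exceeds this are trimmed off (default 250); a genuine region boundary
#'   is candidate-dense, while an isolated flanking false positive chained
#'   across `max_gap` is not.
#' @return data frame `region_id`, `chrom`, `start`, `end`,
#'   `n_candidate_cpgs`, `n_tested_cpgs`.
#' @export
cluster_asm_regions <- function(asm_table, max_gap = 1000L,
                                min_cluster_size = 5L, min_purity = 0.5,
                                edge_gap = 250L) {
  empty <- data.frame(region_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_candidate_cpgs = integer(0),
                      n_tested_cpgs = integer(0))
  cand <- asm_table[asm_table$candidate %in% TRUE, c("chrom", "pos")]
  if (!nrow(cand)) return(empty)
  cand <- cand[order(cand$chrom, cand$pos), ]
  tested <- asm_table[asm_table$tested %in% TRUE, c("chrom", "pos")]

  rows <- list()
  for (ch in unique(cand$chrom)) {
    p <- cand$pos[cand$chrom == ch]
    tp <- tested$pos[tested$chrom == ch]
    brk <- c(0L, which(diff(p) > max_gap), length(p))
    for (j in seq_len(length(brk) - 1L)) {
      chain <- p[(brk[j] + 1L):brk[j + 1L]]
      while (length(chain) >= 2L && chain[2L] - chain[1L] > edge_gap)
        chain <- chain[-1L]
      while (length(chain) >= 2L &&
             chain[length(chain)] - chain[length(chain) - 1L] > edge_gap)
        chain <- chain[-length(chain)]
      if (length(chain) < min_cluster_size) next
      n_tested <- sum(tp >= chain[1] & tp <= chain[length(chain)])
      if (length(chain) / n_tested < min_purity) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = chain[1], end = chain[length(chain)] + 2L,
        n_candidate_cpgs = length(chain), n_tested_cpgs = n_tested)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), ]
  out <- cbind(region_id = sprintf("asm_%03d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Classify ASM regions by distance to known imprinted genes
#'
#' A region within `max_distance` (default 1 Mb) of a known imprinted gene
#' interval is classified `imprinted`, otherwise `non_imprinted`; distance
#' is measured between closest interval edges (0 when overlapping). With no
#' annotation supplied (`NULL`) the class is `unannotated`.
#'
#' @param regions region table (`chrom`, `start`, `end`).
#' @param imprinted_genes interval data frame of known imprinted genes; may
#'   have zero rows (then everything is `non_imprinted`).
#' @param max_distance classification distance in bp.
#' @return `regions` with a `class` column.
#' @export
classify_regions <- function(regions, imprinted_genes, max_distance = 1e6) {
  if (!nrow(regions)) {
    regions$class <- character(0)
    return(regions)
  }
  if (is.null(imprinted_genes)) {
    regions$class <- "unannotated"
    return(regions)
  }
  regions$class <- "non_imprinted"
  if (nrow(imprinted_genes)) {
    d <- GenomicRanges::distanceToNearest(as_granges(regions),
                                          as_granges(imprinted_genes))
    q <- S4Vectors::queryHits(d)
    near <- q[S4Vectors::mcols(d)$distance <= max_distance]
    regions$class[near] <- "imprinted"
  }
  regions
}

#' Characterize ASM regions
#'
#' Per-region size, tested-CpG density, mean per-allele methylation levels,
#' absolute between-allele difference, overall level and CpG-island overlap,
#' plus a per-class summary (mean, SD, range of the absolute difference) as
#' the `"class_summary"` attribute.
#'
#' @param regions classified region table.
#' @param asm_table per-CpG allelic table from [asm_test_cpgs()].
#' @param islands optional CpG-island intervals.
#' @return augmented region data frame; `attr(, "class_summary")` holds the
#'   per-class statistics.
#' @export
characterize_regions <- function(regions, asm_table, islands = NULL) {
  if (!nrow(regions)) return(regions)
  tested <- asm_table[asm_table$tested %in% TRUE, ]
  n <- nrow(regions)
  regions$size <- regions$end - regions$start
  regions$cpg_density <- NA_real_
  regions$pat_mean <- NA_real_; regions$mat_mean <- NA_real_
  regions$abs_diff <- NA_real_; regions$mean_level <- NA_real_
  for (i in seq_len(n)) {
    sel <- tested$chrom == regions$chrom[i] &
      tested$pos >= regions$start[i] & tested$pos < regions$end[i]
    if (!any(sel)) next
    regions$pat_mean[i] <- mean(tested$pat_level[sel], na.rm = TRUE)
    regions$mat_mean[i] <- mean(tested$mat_level[sel], na.rm = TRUE)
    tot_C <- tested$pat_C[sel] + tested$mat_C[sel]
    tot <- tot_C + tested$pat_T[sel] + tested$mat_T[sel]
    regions$mean_level[i] <- mean(tot_C / tot)
    regions$cpg_density[i] <- sum(sel) / regions$size[i]
  }
  regions$abs_diff <- abs(regions$pat_mean - regions$mat_mean)
  regions$island_overlap <- if (!is.null(islands))
    overlaps_any(regions, islands) else NA
  if ("class" %in% names(regions)) {
    cs <- do.call(rbind, lapply(split(regions, regions$class), function(g) {
      data.frame(class = g$class[1], n = nrow(g),
                 mean_abs_diff = mean(g$abs_diff, na.rm = TRUE),
                 sd_abs_diff = sd(g$abs_diff),
                 min_abs_diff = suppressWarnings(min(g$abs_diff, na.rm = TRUE)),
                 max_abs_diff = suppressWarnings(max(g$abs_diff, na.rm = TRUE)),
                 mean_level = mean(g$mean_level, na.rm = TRUE),
                 mean_cpg_density = mean(g$cpg_density, na.rm = TRUE))
    }))
    rownames(cs) <- NULL
    attr(regions, "class_summary") <- cs
  }
  regions
}

#' Run the full allele-specific methylation scan
#'
#' End-to-end ASM detection on a pooled group of samples: read trimming,
#' parental-origin assignment, allelic pooling, the per-CpG Fisher exact
#' test with the minimum per-allele coverage rule, candidate selection,
#' label-permutation FDR, clustering into regions, and classification
#' against known imprinted genes.
#'
#' @param read_sets list of `read_set` objects (conventionally the
#'   controls).
#' @param ref the `ref_bundle`.
#' @param het_snps heterozygous SNP table (see
#'   [assign_parental_origin()]).
#' @param imprinted_genes known-imprinted-gene intervals (or `NULL`).
#' @param min_allele_cov,alpha testing parameters (defaults 4 and 0.01).
#' @param max_gap,min_cluster_size,min_purity,edge_gap clustering
#'   parameters (see [cluster_asm_regions()]).
#' @param perm_reps number of permutation replicates for the FDR (default
#'   1).
#' @param seed seed for the permutation(s).
#' @return object of class `asm_scan`: list with `cpgs` (tested table),
#'   `regions` (characterized), `n_tested`, `n_obs_candidates`,
#'   `n_perm_candidates` (one per replicate), `fdr`, and the parameters.
#' @export
asm_scan <- function(read_sets, ref, het_snps, imprinted_genes = NULL,
                     min_allele_cov = 4L, alpha = 0.01, max_gap = 1000L,
                     min_cluster_size = 5L, min_purity = 0.5, edge_gap = 250L,
                     perm_reps = 1L, seed = 1L) {
  if (inherits(read_sets, "read_set")) read_sets <- list(read_sets)
  read_sets <- lapply(read_sets, function(rs)
    if (rs$trimmed) rs else trim_reads(rs))
  assignments <- lapply(read_sets, assign_parental_origin, het_snps = het_snps)

  allelic <- pool_allelic_counts(read_sets, assignments, ref, snps = het_snps)
  cpgs <- asm_test_cpgs(allelic, min_allele_cov, alpha)
  n_obs <- sum(cpgs$candidate)

  n_perm <- integer(perm_reps)
  for (r in seq_len(perm_reps)) {
    perm <- permute_alleles(assignments, seed = seed + r - 1L)
    pal <- pool_allelic_counts(read_sets, perm, ref, snps = het_snps)
    pcp <- asm_test_cpgs(pal, min_allele_cov, alpha)
    n_perm[r] <- sum(pcp$candidate)
  }
  fdr <- if (n_obs > 0) estimate_fdr(n_obs, n_perm) else NA_real_

  regions <- cluster_asm_regions(cpgs, max_gap, min_cluster_size, min_purity,
                                 edge_gap)
  regions <- classify_regions(regions, imprinted_genes)
  regions <- characterize_regions(regions, cpgs, islands = ref$cpg_islands)

  structure(list(cpgs = cpgs, regions = regions,
                 n_tested = sum(cpgs$tested), n_obs_candidates = n_obs,
                 n_perm_candidates = n_perm, fdr = fdr,
                 params = list(min_allele_cov = min_allele_cov,
                               alpha = alpha, max_gap = max_gap,
                               min_cluster_size = min_cluster_size,
                               min_purity = min_purity, edge_gap = edge_gap,
                               perm_reps = perm_reps, seed = seed)),
            class = "asm_scan")
}

#' @export
print.asm_scan <- function(x, ...) {
  cat("Allele-specific methylation scan\n")
  cat(sprintf("  CpGs tested (>=%dx per allele): %s\n",
              x$params$min_allele_cov, format(x$n_tested, big.mark = ",")))
  cat(sprintf("  candidates at p < %.3g: %s (permuted: %s) -> FDR %s\n",
              x$params$alpha, format(x$n_obs_candidates, big.mark = ","),
              paste(x$n_perm_candidates, collapse = "/"),
              ifelse(is.na(x$fdr), "n/a", sprintf("%.1f%%", 100 * x$fdr))))
  cat(sprintf("  regions: %d (%d imprinted, %d non-imprinted)\n",
              nrow(x$regions), sum(x$regions$class == "imprinted"),
              sum(x$regions$class == "non_imprinted")))
  invisible(x)
}

#' @export
summary.asm_scan <- function(object, ...) {
  print(object)
  cs <- attr(object$regions, "class_summary")
  if (!is.null(cs)) {
    cat("  per-class |pat - mat| difference:\n")
    for (i in seq_len(nrow(cs)))
      cat(sprintf("    %-14s n=%2d  mean %.3f  sd %.3f  range [%.3f, %.3f]\n",
                  cs$class[i], cs$n[i], cs$mean_abs_diff[i], cs$sd_abs_diff[i],
                  cs$min_abs_diff[i], cs$max_abs_diff[i]))
  }
  invisible(object)
}
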