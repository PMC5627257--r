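#' DEGs spatially associated with DMRs
#'
#' A DEG is associated when any DMR overlaps its gene interval extended by
#' `extension` bp on both sides (half-open, >= 1 bp overlap).
#'
#' @param degs data frame with `gene_id`, `chrom`, `start`, `end`.
#' @param dmrs interval data frame (`chrom`, `start`, `end`).
#' @param extension bp added to each side of the gene (conventionally 5000
#'   or 20000).
#' @param chroms chromosome namespace; DMRs on other chromosomes are skipped
#'   with a warning (defaults to the DEGs' chromosomes).
#' @return character vector of associated `gene_id`s.
#' @export
associate <- function(degs, dmrs, extension = 5000L,
                      chroms = unique(degs$chrom)) {
  check_interval_df(degs, "degs"); check_interval_df(dmrs, "dmrs")
  if (!nrow(degs) || !nrow(dmrs)) return(character(0))
  unknown <- !dmrs$chrom %in% chroms
  if (any(unknown)) {
    warning(sum(unknown), " DMR(s) on unknown chromosomes skipped")
    dmrs <- dmrs[!unknown, , drop = FALSE]
    if (!nrow(dmrs)) return(character(0))
  }
  ext <- data.frame(chrom = degs$chrom,
                    start = pmax(0L, degs$start - as.integer(extension)),
                    end = degs$end + as.integer(extension))
  hit <- overlaps_any(ext, dmrs)
  unique(degs$gene_id[hit])
}

#' Percent of DEGs associated with a DMR
#'
#' @inheritParams associate
#' @return 100 x associated / total DEGs.
#' @export
#' @examples
#' # 3 associated DEGs out of 200 -> 1.5
deg_dmr_linkage_fraction <- function(degs, dmrs, extension = 5000L) {
  if (!nrow(degs)) stop("no DEGs supplied")
  100 * length(associate(degs, dmrs, extension)) / nrow(degs)
}

#' Shuffle DMRs within their chromosomes
#'
#' Places each DMR uniformly at random on its own chromosome, preserving its
#' length and avoiding assembly gaps, by rejection sampling (at most
#' `max_tries` draws per interval and replicate). Shuffled intervals may
#' overlap each other.
#'
#' @param dmrs interval data frame.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param gaps optional gap intervals excluded from placement.
#' @param seed integer seed.
#' @param n_reps number of independent shuffle replicates.
#' @param max_tries rejection-sampling cap per interval.
#' @return data frame `rep_id`, `dmr_id`, `chrom`, `start`, `end`.
#' @export
shuffle_dmrs <- function(dmrs, chrom_lengths, gaps = NULL, seed = NULL,
                         n_reps = 1L, max_tries = 10000L) {
  check_interval_df(dmrs, "dmrs")
  if (!is.null(seed)) set.seed(seed)
  if (!all(dmrs$chrom %in% names(chrom_lengths)))
    stop("DMR chromosome missing from chrom_lengths")
  n <- nrow(dmrs)
  if (n == 0L)
    return(data.frame(rep_id = integer(0), dmr_id = integer(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0)))
  w <- dmrs$end - dmrs$start
  L <- as.numeric(chrom_lengths[dmrs$chrom])
  if (any(w > L))
    stop("placement error: DMR longer than its chromosome (interval #",
         which(w > L)[1], ")")

  out <- data.table::data.table(
    rep_id = rep(seq_len(n_reps), each = n),
    dmr_id = rep(seq_len(n), n_reps),
    chrom = rep(dmrs$chrom, n_reps),
    w = rep(w, n_reps), L = rep(L, n_reps),
    start = NA_integer_)
  todo <- seq_len(nrow(out))
  gp <- if (!is.null(gaps) && nrow(gaps))
    data.table::as.data.table(gaps[, c("chrom", "start", "end")]) else NULL
  if (!is.null(gp)) {
    gp[, end := end - 1L]   # foverlaps uses closed ends; ours are half-open
    data.table::setkey(gp, chrom, start, end)
  }
  tries <- 0L
  while (length(todo)) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("placement error: no gap-free position found for interval #",
           out$dmr_id[todo[1]], " (chromosome ", out$chrom[todo[1]],
           ") after ", max_tries, " tries")
    cand <- as.integer(floor(runif(length(todo)) * (out$L[todo] - out$w[todo] + 1)))
    if (is.null(gp)) {
      out$start[todo] <- cand
      todo <- integer(0)
    } else {
      q <- data.table::data.table(chrom = out$chrom[todo], start = cand,
                                  end = cand + out$w[todo] - 1L)
      ov <- data.table::foverlaps(q, gp, type = "any", which = TRUE,
                                  mult = "first")
      ok <- is.na(ov)
      out$start[todo[ok]] <- cand[ok]
      todo <- todo[!ok]
    }
  }
  out[, end := start + w]
  data.table::setDF(out)
  out[, c("rep_id", "dmr_id", "chrom", "start", "end")]
}

#' Chi-square goodness of fit for an observed vs expected associated count
#'
#' Two-cell goodness-of-fit statistic on \{associated, not associated\} with
#' one degree of freedom:
#' chi2 = (O - E)^2 / E + ((N - O) - (N - E))^2 / (N - E).
#'
#' @param observed observed associated-DEG count O.
#' @param expected expected count E (mean over shuffles).
#' @param n_total total DEG count N.
#' @return list with `chi2` and `p_value` (both NA when E or N - E is 0).
#' @export
association_chisq <- function(observed, expected, n_total) {
  if (expected <= 0 || expected >= n_total)
    return(list(chi2 = NA_real_, p_value = NA_real_))
  chi2 <- (observed - expected)^2 / expected +
    (observed - expected)^2 / (n_total - expected)
  list(chi2 = chi2, p_value = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Shuffle-based expectation and test of DMR-DEG association
#'
#' Counts the observed DEGs associated with the DMRs, re-places the DMRs
#' uniformly within their chromosomes (length preserved, gaps excluded)
#' `n_shuffles` times, uses the mean associated count over shuffles as the
#' expected count, and tests observed vs expected with the two-cell
#' chi-square ([association_chisq()]). When the chi-square is undefined
#' (degenerate expectation) the reported p-value falls back to the exact
#' permutation tail probability, flagged in `method`.
#'
#' @inheritParams associate
#' @inheritParams shuffle_dmrs
#' @param n_shuffles number of shuffles (conventionally 1000).
#' @return object of class `assoc_result`: `extension`, `n_deg_total`,
#'   `n_observed`, `n_expected`, `chi2`, `p_value`, `perm_p` (fraction of
#'   shuffles with a count >= observed), `n_shuffles`, `method`.
#' @export
permutation_expectation <- function(degs, dmrs, chrom_lengths, gaps = NULL,
                                    extension = 5000L, n_shuffles = 1000L,
                                    seed = NULL) {
  check_interval_df(degs, "degs")
  observed <- length(associate(degs, dmrs, extension,
                               chroms = names(chrom_lengths)))
  sh <- shuffle_dmrs(dmrs, chrom_lengths, gaps, seed = seed,
                     n_reps = n_shuffles)

  # batched overlap of all shuffled replicates against the extended genes
  ext <- data.table::data.table(
    gene_id = degs$gene_id, chrom = degs$chrom,
    start = pmax(0L, degs$start - as.integer(extension)),
    end = degs$end + as.integer(extension) - 1L)   # closed end for foverlaps
  data.table::setkey(ext, chrom, start, end)
  shd <- data.table::as.data.table(sh)
  shd[, end := end - 1L]
  ov <- data.table::foverlaps(shd, ext, type = "any", nomatch = NULL)
  counts <- rep(0L, n_shuffles)
  if (nrow(ov)) {
    cnt <- ov[, list(n = data.table::uniqueN(gene_id)), by = rep_id]
    counts[cnt$rep_id] <- cnt$n
  }
  expected <- mean(counts)
  perm_p <- mean(counts >= observed)

  ct <- association_chisq(observed, expected, nrow(degs))
  method <- if (is.na(ct$chi2)) "exact permutation tail (degenerate expectation)"
            else "two-cell chi-square, 1 df"
  p <- if (is.na(ct$chi2)) perm_p else ct$p_value
  structure(list(extension = extension, n_deg_total = nrow(degs),
                 n_observed = observed, n_expected = expected,
                 chi2 = ct$chi2, p_value = p, perm_p = perm_p,
                 n_shuffles = n_shuffles, method = method),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("DMR-DEG association (extension %s bp, %d shuffles)\n",
              format(x$extension, big.mark = ","), x$n_shuffles))
  cat(sprintf("  associated DEGs: %d observed vs %.2f expected of %d (%.1f%%)\n",
              x$n_observed, x$n_expected, x$n_deg_total,
              100 * x$n_observed / x$n_deg_total))
  cat(sprintf("  %s: chi2 = %s, p = %.3g%s\n", x$method,
              ifelse(is.na(x$chi2), "n/a", sprintf("%.2f", x$chi2)),
              x$p_value,
              if (!is.na(x$p_value) && x$p_value < 0.01) " (*p < 0.01)" else ""))
  invisible(x)
}

#' Intersection of two DMR sets
#'
#' All >= 1 bp overlaps between two interval sets, reported as their
#' intersection intervals.
#'
#' @param dmrs_a,dmrs_b interval data frames.
#' @return data frame `chrom`, `start`, `end`, `a_row`, `b_row` (row indices
#'   of the overlapping pair).
#' @export
dmr_overlap <- function(dmrs_a, dmrs_b) {
  check_interval_df(dmrs_a, "dmrs_a"); check_interval_df(dmrs_b, "dmrs_b")
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), a_row = integer(0),
                      b_row = integer(0))
  if (!nrow(dmrs_a) || !nrow(dmrs_b)) return(empty)
  hits <- GenomicRanges::findOverlaps(as_granges(dmrs_a), as_granges(dmrs_b))
  if (!length(hits)) return(empty)
  qa <- S4Vectors::queryHits(hits); qb <- S4Vectors::subjectHits(hits)
  data.frame(chrom = dmrs_a$chrom[qa],
             start = pmax(dmrs_a$start[qa], dmrs_b$start[qb]),
             end = pmin(dmrs_a$end[qa], dmrs_b$end[qb]),
             a_row = qa, b_row = qb)
}

#' Methylation difference in the TSS window of strong DEGs
#'
#' For every gene with |log2 fold-change| at least `min_abs_l2fc`, the mean
#' per-CpG methylation difference (case minus control) over covered CpGs in
#' the strand-aware TSS window (-`upstream`, +`downstream`), default
#' -1.5 kb to +500 bp. Samples within each group are pooled at the count
#' level before levels are computed.
#'
#' @param degs gene table with `gene_id`, `chrom`, `strand`, `tss` and
#'   `log2_fold_change`.
#' @param cpg_case,cpg_control per-CpG tables (or lists of per-sample
#'   tables) with `chrom`, `pos`, `n_C`, `n_T`.
#' @param upstream,downstream window bounds relative to the TSS in
#'   transcription direction.
#' @param min_abs_l2fc fold-change filter (default 1, i.e. >= 2-fold).
#' @return data frame `gene_id`, `log2_fold_change`, `delta`,
#'   `n_cpgs_case`, `n_cpgs_control`; `delta` is NA for windows without
#'   covered CpGs.
#' @export
tss_window_meth_diff <- function(degs, cpg_case, cpg_control,
                                 upstream = 1500L, downstream = 500L,
                                 min_abs_l2fc = 1) {
  pool <- function(tabs) {
    if (is.data.frame(tabs)) tabs <- list(tabs)
    x <- data.table::rbindlist(lapply(tabs, function(t)
      data.table::as.data.table(t[, c("chrom", "pos", "n_C", "n_T")])))
    x <- x[, list(n_C = sum(n_C), n_T = sum(n_T)), by = list(chrom, pos)]
    x[, level := methylation_level(n_C, n_T)]
    x
  }
  ca <- pool(cpg_case); co <- pool(cpg_control)
  g <- degs[abs(degs$log2_fold_change) >= min_abs_l2fc, , drop = FALSE]
  out <- data.frame(gene_id = g$gene_id,
                    log2_fold_change = g$log2_fold_change,
                    delta = NA_real_, n_cpgs_case = 0L, n_cpgs_control = 0L)
  for (i in seq_len(nrow(g))) {
    if (g$strand[i] == "+") {
      ws <- g$tss[i] - upstream; we <- g$tss[i] + downstream
    } else {
      ws <- g$tss[i] - downstream + 1L; we <- g$tss[i] + upstream + 1L
    }
    mca <- ca[chrom == g$chrom[i] & pos >= ws & pos < we & !is.na(level)]
    mco <- co[chrom == g$chrom[i] & pos >= ws & pos < we & !is.na(level)]
    out$n_cpgs_case[i] <- nrow(mca); out$n_cpgs_control[i] <- nrow(mco)
    if (nrow(mca) && nrow(mco))
      out$delta[i] <- mean(mca$level) - mean(mco$level)
  }
  out
}

#' Naive fixed-window DMR scanner (rough plumbing)
#'
#' Slides non-overlapping fixed windows over the genome and flags those
#' where case and control mean CpG methylation differ by at least
#' `min_delta` with at least `min_cpgs` covered CpGs in both, merging
#' adjacent flagged windows. This is deliberately crude plumbing to produce
#' DMR-like intervals from per-CpG tables when no external DMR caller is in
#' the loop; it is not a smoothing-based DMR method and is excluded from any
#' validation claim this package makes.
#'
#' @param cpg_case,cpg_control per-CpG tables (`chrom`, `pos`, `level`).
#' @param window window width in bp (default 500).
#' @param min_delta minimum |case - control| mean difference.
#' @param min_cpgs minimum covered CpGs per window in each group.
#' @return interval data frame `chrom`, `start`, `end`, `mean_diff`,
#'   `n_cpgs`.
#' @export
scan_dmrs_naive <- function(cpg_case, cpg_control, window = 500L,
                            min_delta = 0.2, min_cpgs = 5L) {
  ca <- data.table::as.data.table(cpg_case)
  co <- data.table::as.data.table(cpg_control)
  ca[, bin := pos %/% window]; co[, bin := pos %/% window]
  a <- ca[!is.na(level), list(m_case = mean(level), n_case = .N),
          by = list(chrom, bin)]
  b <- co[!is.na(level), list(m_ctl = mean(level), n_ctl = .N),
          by = list(chrom, bin)]
  x <- merge(a, b, by = c("chrom", "bin"))
  x <- x[n_case >= min_cpgs & n_ctl >= min_cpgs &
           abs(m_case - m_ctl) >= min_delta]
  if (!nrow(x))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), mean_diff = numeric(0),
                      n_cpgs = integer(0)))
  data.table::setorder(x, chrom, bin)
  x[, grp := cumsum(c(1L, diff(bin) > 1L | head(chrom, -1) != tail(chrom, -1)))]
  out <- x[, list(chrom = chrom[1], start = as.integer(bin[1] * window),
                  end = as.integer((bin[.N] + 1L) * window),
                  mean_diff = mean(m_case - m_ctl),
                  n_cpgs = sum(pmin(n_case, n_ctl))), by = grp]
  out[, grp := NULL]
  data.table::setDF(out)
  out
}
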