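#' Trim read ends from the call stream
#'
#' Drops every SNP and CpG call whose covered base lies in the first
#' `trim_head` or last `trim_tail` positions of its read, in read
#' orientation (5'->3' of the sequenced mate). Read intervals themselves are
#' unchanged. Reads shorter than `trim_head + trim_tail + 1` lose all their
#' calls. This removes the read-end methylation bias before any level is
#' computed.
#'
#' The covered base of a CpG call is the plus-strand C for a plus-strand
#' read and the G position (plus-strand C position + 1) for a minus-strand
#' read; SNP calls cover their own position.
#'
#' @param rs a `read_set` from [simulate_reads()] or [read_reads_tsv()].
#' @param trim_head,trim_tail bases removed from the 5' / 3' read end
#'   (defaults 3 and 2).
#' @return The read set with trimmed call tables and `trimmed = TRUE`.
#' @export
trim_reads <- function(rs, trim_head = 3L, trim_tail = 2L) {
  stopifnot(inherits(rs, "read_set"))
  trim_one <- function(calls, cov_offset) {
    if (!nrow(calls)) return(calls)
    covbase <- calls$pos + cov_offset
    off <- ifelse(calls$strand == "+", covbase - calls$start,
                  calls$end - 1L - covbase)
    len <- calls$end - calls$start
    calls[off >= trim_head & off < len - trim_tail]
  }
  cpg <- rs$cpg_calls
  if (nrow(cpg)) {
    covbase <- cpg$pos + ifelse(cpg$strand == "+", 0L, 1L)
    off <- ifelse(cpg$strand == "+", covbase - cpg$start,
                  cpg$end - 1L - covbase)
    len <- cpg$end - cpg$start
    rs$cpg_calls <- cpg[off >= trim_head & off < len - trim_tail]
  }
  rs$snp_calls <- trim_one(rs$snp_calls, 0L)
  rs$trimmed <- TRUE
  rs
}

#' Per-CpG methylation level
#'
#' The ratio of "C" read calls to total ("C" plus "T") calls at a CpG.
#' Undefined (NA) at zero coverage.
#'
#' @param n_C,n_T non-negative counts (vectors recycle).
#' @return numeric vector of levels in \[0, 1\], NA where `n_C + n_T == 0`.
#' @export
#' @examples
#' methylation_level(3, 1)   # 0.75
#' methylation_level(0, 0)   # NA
methylation_level <- function(n_C, n_T) {
  if (any(n_C < 0) || any(n_T < 0)) stop("counts must be non-negative")
  tot <- n_C + n_T
  ifelse(tot > 0, n_C / tot, NA_real_)
}

#' Pile up CpG calls into a per-CpG methylation table
#'
#' Sums the calls from the plus and minus strands of each symmetric CpG into
#' one record keyed by the plus-strand C position. CpGs whose dinucleotide
#' overlaps a provided SNP are excluded (only sites with consensus CpG
#' context on both parental alleles are kept). Calls at positions that are
#' not a reference CpG (or on unknown chromosomes, e.g. the spike-in) are
#' rejected in strict mode, otherwise skipped with a message.
#'
#' @param rs a (preferably trimmed) `read_set`, or a list of them whose call
#'   streams are pooled.
#' @param ref the `ref_bundle` supplying reference CpG positions.
#' @param snps optional data frame of SNPs with `chrom`, `pos` columns
#'   (0-based); CpGs overlapping any of them are dropped.
#' @param strict error (instead of skip) on non-CpG-context calls.
#' @param min_cov minimum merged coverage to keep a record (default 1; see
#'   [coverage_filter()] for the conventional >= 5 filter).
#' @return data frame `chrom`, `pos`, `n_C`, `n_T`, `level`, sorted by
#'   position.
#' @export
pileup_cpgs <- function(rs, ref, snps = NULL, strict = FALSE, min_cov = 1L) {
  stopifnot(inherits(ref, "ref_bundle"))
  if (inherits(rs, "read_set")) rs <- list(rs)
  calls <- data.table::rbindlist(lapply(rs, function(x) {
    stopifnot(inherits(x, "read_set"))
    x$cpg_calls
  }))
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      n_C = integer(0), n_T = integer(0), level = numeric(0))
  if (!nrow(calls)) return(empty)

  # calls on chromosomes outside the reference (e.g. the spike-in channel)
  # are not methylome calls; drop them silently
  known <- calls$chrom %in% ref$chrom_names
  calls <- calls[known]
  if (!nrow(calls)) return(empty)
  in_context <- rep(TRUE, nrow(calls))
  for (ch in unique(calls$chrom)) {
    i <- which(calls$chrom == ch)
    sites <- ref$cpg_sites[[ch]]
    hit <- findInterval(calls$pos[i], sites)
    in_context[i] <- hit > 0L & sites[pmax(hit, 1L)] == calls$pos[i]
  }
  n_bad <- sum(!in_context)
  if (n_bad) {
    if (strict)
      stop(n_bad, " call(s) at non-CpG reference positions")
    message("pileup_cpgs: skipped ", n_bad,
            " call(s) outside reference CpG context")
    calls <- calls[in_context]
  }
  if (!nrow(calls)) return(empty)

  if (!is.null(snps) && nrow(snps)) {
    # a CpG [pos, pos+2) overlaps a SNP at s when s == pos or s == pos + 1
    bad <- data.table::data.table(
      chrom = rep(snps$chrom, 2L),
      pos = c(as.integer(snps$pos), as.integer(snps$pos) - 1L))
    calls <- calls[!bad, on = c("chrom", "pos")]
  }
  if (!nrow(calls)) return(empty)

  tab <- calls[call %in% c("C", "T"),
               list(n_C = sum(call == "C"), n_T = sum(call == "T")),
               by = list(chrom, pos)]
  tab <- tab[n_C + n_T >= min_cov]
  data.table::setorder(tab, chrom, pos)
  tab[, level := methylation_level(n_C, n_T)]
  data.table::setDF(tab)
  tab
}

#' Estimate the bisulfite conversion rate from spike-in reads
#'
#' The unmethylated lambda spike-in should read all-"T"; the conversion rate
#' is the fraction of its cytosine calls that did, T / (C + T).
#'
#' @param rs a `read_set` (or list of them).
#' @param spike_chrom chromosome name of the spike-in (default `"lambda"`).
#' @return conversion rate in \[0, 1\]; NA with a warning when the read set
#'   carries no spike-in cytosine calls.
#' @export
#' @examples
#' # 9931 converted and 69 unconverted cytosines -> 99.31%
#' # estimate_conversion_rate() computes T / (C + T) over spike-in calls
estimate_conversion_rate <- function(rs, spike_chrom = "lambda") {
  if (inherits(rs, "read_set")) rs <- list(rs)
  calls <- data.table::rbindlist(lapply(rs, `[[`, "cpg_calls"))
  if (nrow(calls)) calls <- calls[chrom == spike_chrom]
  nC <- sum(calls$call == "C"); nT <- sum(calls$call == "T")
  if (nC + nT == 0L) {
    warning("no spike-in cytosine calls; conversion rate undefined")
    return(NA_real_)
  }
  nT / (nC + nT)
}

#' Filter a per-CpG table on merged coverage
#'
#' Keeps records covered by at least `min_cov` reads after strand merging
#' (the conventional threshold is 5).
#'
#' @param tab per-CpG table from [pileup_cpgs()].
#' @param min_cov minimum `n_C + n_T` (>= 1).
#' @return the filtered table.
#' @export
coverage_filter <- function(tab, min_cov = 5L) {
  stopifnot(min_cov >= 1L)
  tab[tab$n_C + tab$n_T >= min_cov, , drop = FALSE]
}

#' Genome-wide methylation summary
#'
#' Histogram of per-CpG levels over ten equal bins, overall and CpG-island
#' means, and a bimodality flag: more mass outside \[0.2, 0.8\] than inside,
#' with both tails actually occupied (at least 5% of CpGs below 0.2 and 5%
#' above 0.8) so a single spike at one extreme does not count as bimodal.
#'
#' @param tab per-CpG table (needs a defined `level`).
#' @param islands optional CpG-island intervals (`chrom`, `start`, `end`).
#' @return list of class `meth_summary`: `histogram` (counts per bin),
#'   `breaks`, `mean`, `island_mean`, `non_island_mean`, `bimodal`,
#'   `n_cpgs`.
#' @export
methylation_summary <- function(tab, islands = NULL) {
  lv <- tab$level[!is.na(tab$level)]
  if (!length(lv)) stop("no CpGs with defined methylation level")
  breaks <- seq(0, 1, by = 0.1)
  h <- table(cut(lv, breaks, include.lowest = TRUE, right = FALSE))
  mid <- mean(lv >= 0.2 & lv <= 0.8)
  island_mean <- NA_real_; non_island_mean <- NA_real_
  if (!is.null(islands) && nrow(islands)) {
    in_isl <- logical(nrow(tab))
    for (ch in unique(tab$chrom)) {
      i <- tab$chrom == ch
      in_isl[i] <- pos_in_intervals(tab$pos[i],
                                    islands[islands$chrom == ch, ])
    }
    island_mean <- mean(tab$level[in_isl], na.rm = TRUE)
    non_island_mean <- mean(tab$level[!in_isl], na.rm = TRUE)
  }
  structure(list(histogram = as.integer(h), breaks = breaks, mean = mean(lv),
                 island_mean = island_mean,
                 non_island_mean = non_island_mean,
                 bimodal = mid < (1 - mid) &&
                   mean(lv < 0.2) >= 0.05 && mean(lv > 0.8) >= 0.05,
                 n_cpgs = length(lv)),
            class = "meth_summary")
}

#' @export
print.meth_summary <- function(x, ...) {
  cat(sprintf("Methylation summary over %s CpGs: mean %.3f (%s)\n",
              format(x$n_cpgs, big.mark = ","), x$mean,
              if (x$bimodal) "bimodal" else "not bimodal"))
  if (!is.na(x$island_mean))
    cat(sprintf("  CpG-island mean %.3f vs non-island %.3f\n",
                x$island_mean, x$non_island_mean))
  lab <- sprintf("[%.1f,%.1f)", x$breaks[-11], x$breaks[-1])
  cat("  histogram:\n")
  for (i in seq_along(lab))
    cat(sprintf("    %-10s %s\n", lab[i],
                strrep("#", round(30 * x$histogram[i] / max(x$histogram)))))
  invisible(x)
}
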