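# shared internal helpers -------------------------------------------------

clamp01 <- function(x) pmin(1, pmax(0, x))

# 0-based half-open data.frame -> GRanges (1-based closed)
as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# overlap indicator for interval df `x` against df `y`; both 0-based half-open
overlaps_any <- function(x, y) {
  if (nrow(y) == 0L) return(rep(FALSE, nrow(x)))
  if (nrow(x) == 0L) return(logical(0))
  hits <- GenomicRanges::findOverlaps(as_granges(x), as_granges(y))
  out <- rep(FALSE, nrow(x))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

check_interval_df <- function(df, what = "interval table") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop(what, " must have columns chrom, start, end")
  if (nrow(df) && any(df$end < df$start))
    stop(what, ": end must be >= start")
  invisible(df)
}

#' Jaccard index between two genomic intervals
#'
#' Overlap divided by union length, both intervals 0-based half-open on the
#' same chromosome. Returns 0 for intervals on different chromosomes.
#'
#' @param chrom_a,start_a,end_a first interval (vectors recycle).
#' @param chrom_b,start_b,end_b second interval.
#' @return numeric vector of Jaccard indices in \[0, 1\].
#' @export
#' @examples
#' interval_jaccard("chr1", 0, 100, "chr1", 50, 150)  # 1/3
interval_jaccard <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  inter <- pmax(0, pmin(end_a, end_b) - pmax(start_a, start_b))
  un <- (end_a - start_a) + (end_b - start_b) - inter
  out <- ifelse(un > 0, inter / un, 0)
  out[chrom_a != chrom_b] <- 0
  out
}

#' Best-match recovery of planted regions
#'
#' For each truth interval, the maximum Jaccard index against any detected
#' interval. Used to score how well region detection recovers a planted truth
#' set.
#'
#' @param truth,detected interval data frames with `chrom`, `start`, `end`
#'   columns (0-based half-open).
#' @return numeric vector, one best Jaccard per truth row (0 when nothing
#'   detected).
#' @export
region_recovery <- function(truth, detected) {
  check_interval_df(truth, "truth")
  if (nrow(truth) == 0L) return(numeric(0))
  if (is.null(detected) || nrow(detected) == 0L) return(rep(0, nrow(truth)))
  check_interval_df(detected, "detected")
  vapply(seq_len(nrow(truth)), function(i) {
    j <- interval_jaccard(truth$chrom[i], truth$start[i], truth$end[i],
                          detected$chrom, detected$start, detected$end)
    max(j)
  }, numeric(1))
}

# draw one random DNA vector with given base probabilities (A, C, G, T)
random_bases <- function(n, prob) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob)
}

# remove a fraction of CpG dinucleotides by mutating the C to T
deplete_cpgs <- function(bases, prob) {
  if (length(bases) < 2L || prob <= 0) return(bases)
  is_cg <- which(bases[-length(bases)] == "C" & bases[-1L] == "G")
  hit <- is_cg[runif(length(is_cg)) < prob]
  bases[hit] <- "T"
  bases
}

# positions (0-based) of the plus-strand C of each CpG in a sequence string
cpg_positions <- function(seq_string) {
  m <- gregexpr("CG", seq_string, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  as.integer(m) - 1L
}
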