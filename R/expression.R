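#' Five expression groups
#'
#' Group 1 holds genes below the expression floor (silent or near-silent);
#' the remaining genes are split into quartiles of their expression rank
#' (groups 2-5, low to high). Ties are broken by stable input order, so the
#' grouping is invariant under monotone transforms of the expression
#' measure and under input permutation (each gene keeps its group).
#'
#' @param expression numeric vector of normalized abundances (length >= 5).
#' @param floor expression floor below which a gene falls in group 1.
#' @return integer vector of group labels 1..5.
#' @export
expression_groups <- function(expression, floor = 0.1) {
  if (length(expression) < 5L) stop("need at least 5 genes")
  g <- rep(1L, length(expression))
  rest <- which(expression >= floor)
  if (!length(rest)) {
    warning("all genes below the expression floor; single group")
    return(g)
  }
  r <- rank(expression[rest], ties.method = "first")
  g[rest] <- 2L + as.integer(floor((r - 1) * 4 / length(rest)))
  g
}

#' Metagene methylation profile by expression group
#'
#' Mean per-CpG methylation in strand-oriented bins along a fixed upstream
#' flank, the scaled gene body, and a fixed downstream flank, averaged
#' within expression groups. Flanks are binned at `flank_bin` bp; gene
#' bodies are scaled to `n_body_bins` bins regardless of length (genes
#' shorter than `n_body_bins` bp simply populate a subset of body bins).
#' Bins without any covered CpG are reported as NA, not 0.
#'
#' @param cpg_tab per-CpG table (`chrom`, `pos`, `level`).
#' @param genes gene table (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @param groups integer group label per gene (e.g.
#'   [expression_groups()]).
#' @param flank flank span in bp on each side (default 3000).
#' @param n_body_bins scaled gene-body bins (default 100).
#' @param flank_bin flank bin width in bp (default 50).
#' @return data frame of class `metagene_profile`: `bin` (1..total),
#'   `zone` (upstream/body/downstream), `group`, `mean_level`, `n`
#'   (CpG-gene observations in the bin). Attribute `layout` records the bin
#'   arithmetic.
#' @export
metagene_profile <- function(cpg_tab, genes, groups, flank = 3000L,
                             n_body_bins = 100L, flank_bin = 50L) {
  stopifnot(nrow(genes) == length(groups))
  nf <- as.integer(flank / flank_bin)
  total <- 2L * nf + n_body_bins
  tab <- data.table::as.data.table(cpg_tab)[!is.na(level)]

  obs <- list()
  for (i in seq_len(nrow(genes))) {
    gs <- genes$start[i]; ge <- genes$end[i]; glen <- ge - gs
    x <- tab[chrom == genes$chrom[i] & pos >= gs - flank & pos < ge + flank]
    if (!nrow(x)) next
    d5 <- if (genes$strand[i] == "+") x$pos - gs else (ge - 1L) - x$pos
    bin <- integer(nrow(x))
    up <- d5 < 0; dn <- d5 >= glen; body <- !up & !dn
    bin[up] <- 1L + ((d5[up] + flank) %/% flank_bin)
    bin[body] <- nf + 1L + pmin(n_body_bins - 1L,
                                as.integer(d5[body] / glen * n_body_bins))
    bin[dn] <- nf + n_body_bins + 1L + ((d5[dn] - glen) %/% flank_bin)
    keep <- bin >= 1L & bin <= total
    if (!any(keep)) next
    obs[[length(obs) + 1L]] <- data.table::data.table(
      bin = bin[keep], grp = groups[i], level = x$level[keep])
  }
  grid <- data.table::CJ(bin = seq_len(total), group = sort(unique(groups)))
  if (length(obs)) {
    o <- data.table::rbindlist(obs)
    agg <- o[, list(mean_level = mean(level), n = .N),
             by = list(bin, group = grp)]
    grid <- merge(grid, agg, by = c("bin", "group"), all.x = TRUE)
  } else {
    grid[, c("mean_level", "n") := list(NA_real_, NA_integer_)]
  }
  grid[is.na(n), n := 0L]
  grid[, zone := data.table::fifelse(bin <= nf, "upstream",
                  data.table::fifelse(bin <= nf + n_body_bins, "body",
                                      "downstream"))]
  data.table::setorder(grid, group, bin)
  out <- data.table::setDF(grid[, list(bin, zone, group, mean_level, n)])
  attr(out, "layout") <- list(flank = flank, flank_bin = flank_bin,
                              n_flank_bins = nf, n_body_bins = n_body_bins)
  class(out) <- c("metagene_profile", "data.frame")
  out
}

#' Classify promoters by CpG density
#'
#' Computes the CpG observed/expected ratio, `n_CpG * L / (n_C * n_G)` (0
#' when the window has no C or no G), and the GC fraction over sliding
#' sub-windows of the promoter (default 500 bp windows stepped by 50 bp
#' across the strand-aware -700/+200 region around the TSS). A promoter is
#' HCP when any sub-window exceeds both the ratio and GC thresholds
#' (defaults 0.75 and 0.55), LCP when no sub-window exceeds the lower ratio
#' threshold (0.48), otherwise ICP. Windows truncated below one sub-window
#' by a chromosome end are NA. Both counts are strand-symmetric, so the
#' classification does not depend on which strand the sequence is read
#' from.
#'
#' @param ref `ref_bundle` with sequences.
#' @param genes gene table (`chrom`, `strand`, `tss`).
#' @param upstream,downstream promoter window around the TSS (bp).
#' @param subwindow,step sliding sub-window width and step (bp).
#' @param hcp_ratio,hcp_gc,lcp_ratio class thresholds.
#' @return character vector (`"HCP"`, `"ICP"`, `"LCP"` or NA) per gene.
#' @export
classify_promoters <- function(ref, genes, upstream = 700L, downstream = 200L,
                               subwindow = 500L, step = 50L,
                               hcp_ratio = 0.75, hcp_gc = 0.55,
                               lcp_ratio = 0.48) {
  if (is.null(ref$sequences)) stop("reference has no sequence")
  out <- rep(NA_character_, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    L <- ref$chrom_lengths[[genes$chrom[i]]]
    w <- promoter_window(genes$tss[i], genes$strand[i], upstream, downstream, L)
    if (w[2] - w[1] < subwindow) next
    s <- substr(ref$sequences[[genes$chrom[i]]], w[1] + 1L, w[2])
    out[i] <- classify_promoter_seq(s, subwindow, step,
                                    hcp_ratio, hcp_gc, lcp_ratio)
  }
  out
}

# classify one promoter sequence string
classify_promoter_seq <- function(s, subwindow = 500L, step = 50L,
                                  hcp_ratio = 0.75, hcp_gc = 0.55,
                                  lcp_ratio = 0.48) {
  W <- nchar(s)
  if (W < subwindow) return(NA_character_)
  offs <- unique(c(seq(0L, W - subwindow, by = step), W - subwindow))
  hcp <- FALSE; any_mid <- FALSE
  for (o in offs) {
    sub <- substr(s, o + 1L, o + subwindow)
    nC <- nchar(gsub("[^C]", "", sub))
    nG <- nchar(gsub("[^G]", "", sub))
    nCG <- cg_count(sub)
    ratio <- if (nC * nG > 0) nCG * subwindow / (nC * nG) else 0
    gc <- (nC + nG) / subwindow
    if (ratio > hcp_ratio && gc > hcp_gc) hcp <- TRUE
    if (ratio > lcp_ratio) any_mid <- TRUE
  }
  if (hcp) "HCP" else if (!any_mid) "LCP" else "ICP"
}

cg_count <- function(s) {
  m <- gregexpr("CG", s, fixed = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

#' Methylation-expression correlation by promoter class
#'
#' Spearman rank correlation between per-gene mean methylation in a region
#' (promoter -500 bp to the TSS, or the gene body) and expression, reported
#' overall and within each promoter CpG-density class. Genes without a
#' covered CpG in the region are dropped; classes with fewer than
#' `min_genes` informative genes, or with a constant methylation vector,
#' report NA.
#'
#' @param genes gene table (`gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `tss`).
#' @param cpg_tab per-CpG table (`chrom`, `pos`, `level`).
#' @param expression numeric vector of normalized abundances per gene.
#' @param region `"promoter"` (default; -`promoter_upstream` to the TSS) or
#'   `"gene_body"`.
#' @param promoter_class optional character vector of per-gene classes
#'   (e.g. [classify_promoters()]); enables the per-class rows.
#' @param promoter_upstream upstream extent of the promoter region (bp).
#' @param min_genes minimum informative genes per stratum (default 10).
#' @return data frame `stratum`, `n`, `rho`, `p_value`.
#' @export
meth_expr_correlation <- function(genes, cpg_tab, expression,
                                  region = c("promoter", "gene_body"),
                                  promoter_class = NULL,
                                  promoter_upstream = 500L, min_genes = 10L) {
  region <- match.arg(region)
  stopifnot(nrow(genes) == length(expression))
  tab <- data.table::as.data.table(cpg_tab)[!is.na(level)]
  m <- rep(NA_real_, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    if (region == "promoter") {
      if (genes$strand[i] == "+") {
        ws <- genes$tss[i] - promoter_upstream; we <- genes$tss[i]
      } else {
        ws <- genes$tss[i] + 1L; we <- genes$tss[i] + promoter_upstream + 1L
      }
    } else {
      ws <- genes$start[i]; we <- genes$end[i]
    }
    x <- tab[chrom == genes$chrom[i] & pos >= ws & pos < we]
    if (nrow(x)) m[i] <- mean(x$level)
  }

  strata <- list(overall = seq_len(nrow(genes)))
  if (!is.null(promoter_class))
    for (cl in c("HCP", "ICP", "LCP"))
      strata[[cl]] <- which(promoter_class %in% cl)
  rows <- lapply(names(strata), function(nm) {
    idx <- strata[[nm]]
    idx <- idx[!is.na(m[idx])]
    if (length(idx) < min_genes || length(unique(m[idx])) < 2L ||
        length(unique(expression[idx])) < 2L)
      return(data.frame(stratum = nm, n = length(idx), rho = NA_real_,
                        p_value = NA_real_))
    ct <- suppressWarnings(cor.test(m[idx], expression[idx],
                                    method = "spearman"))
    data.frame(stratum = nm, n = length(idx),
               rho = unname(ct$estimate), p_value = ct$p.value)
  })
  do.call(rbind, rows)
}
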