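#' Plant methylation, SNP, DMR and expression truth on a reference
#'
#' Draws everything the read and expression simulators need, and everything
#' the recovery tests compare against: heterozygous SNPs between the two
#' parental haplotypes (with the sire's genotype), per-CpG background
#' methylation from a bimodal mixture (CpG islands hypomethylated), ASM
#' regions with planted between-allele differences (imprinted class centred
#' on 0.73, non-imprinted on 0.51, both alleles averaging 0.5), per-case
#' DMRs, and the DEG list with its DMR-coupling flags.
#'
#' @param ref a [sim_reference()] bundle.
#' @param config the [sim_config()] used to build `ref`.
#' @return An object of class `truth_set`: a list with
#'   \describe{
#'     \item{het_snps}{data frame `chrom`, `pos` (0-based), `pat_base`,
#'       `mat_base`, `sire_genotype` (`"X/X"` when homozygous).}
#'     \item{asm_regions}{data frame `chrom`, `start`, `end` (snapped to the
#'       CpG span), `mu_pat`, `mu_mat`, `abs_diff`, `class`, `n_cpgs`.}
#'     \item{background_meth}{per-chromosome numeric vectors aligned with
#'       `ref$cpg_sites`: the biallelic background methylation level of each
#'       CpG.}
#'     \item{dmrs}{data frame `sample_id`, `chrom`, `start`, `end`, `delta`,
#'       `coupled_gene`.}
#'     \item{deg_truth}{data frame `gene_id`, `chrom`, `start`, `end`,
#'       `is_deg`, `log2_fold_change`, `coupled`, `promoter_meth`.}
#'   }
#' @export
plant_truth <- function(ref, config) {
  stopifnot(inherits(ref, "ref_bundle"))
  set.seed(config$seed + 1L)

  chroms <- ref$chrom_names
  has_seq <- !is.null(ref$sequences)

  ## ---- heterozygous SNPs -------------------------------------------------
  empty_snps <- data.frame(chrom = character(0), pos = integer(0),
                           pat_base = character(0), mat_base = character(0),
                           sire_genotype = character(0))
  het_snps <- empty_snps
  if (has_seq && config$snp_rate > 0) {
    het_snps <- do.call(rbind, lapply(chroms, function(ch) {
      L <- ref$chrom_lengths[[ch]]
      n <- rbinom(1L, L, config$snp_rate)
      if (n == 0L) return(NULL)
      pos <- sort(sample.int(L, n)) - 1L
      pat <- strsplit(ref$sequences[[ch]], "")[[1]][pos + 1L]
      mat <- draw_mat_alleles(pat, config$confounded_fraction)
      sire_het <- runif(n) < config$sire_het_fraction
      data.frame(chrom = ch, pos = pos, pat_base = pat, mat_base = mat,
                 sire_genotype = ifelse(sire_het,
                                        paste(pat, mat, sep = "/"),
                                        paste(pat, pat, sep = "/")))
    }))
    if (is.null(het_snps)) het_snps <- empty_snps
    rownames(het_snps) <- NULL
    # ASM truth regions represent loci detectable by allelic readout: regions
    # without informative SNPs are invisible to any SNP-based detector and
    # would never enter a truth set, so planted segments are guaranteed
    # het-SNP coverage across their span (max inter-SNP gap 150 bp)
    het_snps <- ensure_segment_snps(het_snps, ref, config, max_snp_gap = 150L)
  }

  ## ---- background methylation (bimodal; islands hypomethylated) ----------
  background_meth <- NULL
  if (has_seq) {
    background_meth <- setNames(vector("list", length(chroms)), chroms)
    for (ch in chroms) {
      pos <- ref$cpg_sites[[ch]]
      lv <- numeric(length(pos))
      isl <- ref$cpg_islands[ref$cpg_islands$chrom == ch, ]
      in_isl <- pos_in_intervals(pos, isl)
      lv[in_isl] <- rbeta(sum(in_isl), 1.5, 8)
      n_out <- sum(!in_isl)
      lowmode <- runif(n_out) < 0.25
      lv[!in_isl] <- ifelse(lowmode, rbeta(n_out, 1.5, 8), rbeta(n_out, 8, 1.5))
      background_meth[[ch]] <- lv
    }
    # per-gene promoter methylation: a bimodal state shared by the CpGs of
    # one promoter, so promoters vary across genes (drives the
    # methylation-expression coupling)
    prom_meth <- rep(NA_real_, nrow(ref$genes))
    for (j in seq_len(nrow(ref$genes))) {
      g <- ref$genes[j, ]
      u <- if (runif(1) < 0.5) rbeta(1, 2, 10) else rbeta(1, 10, 2)
      prom_meth[j] <- u
      w <- promoter_window(g$tss, g$strand, 700L, 200L,
                           ref$chrom_lengths[[g$chrom]])
      pos <- ref$cpg_sites[[g$chrom]]
      sel <- pos >= w[1] & pos < w[2]
      background_meth[[g$chrom]][sel] <-
        clamp01(u + rnorm(sum(sel), 0, 0.03))
    }
  } else {
    prom_meth <- rep(NA_real_, nrow(ref$genes))
  }

  ## ---- ASM regions -------------------------------------------------------
  segs <- ref$asm_segments
  asm_regions <- data.frame(chrom = character(0), start = integer(0),
                            end = integer(0), mu_pat = numeric(0),
                            mu_mat = numeric(0), abs_diff = numeric(0),
                            class = character(0), n_cpgs = integer(0))
  if (has_seq && nrow(segs)) {
    rows <- lapply(seq_len(nrow(segs)), function(j) {
      ch <- segs$chrom[j]
      pos <- ref$cpg_sites[[ch]]
      sel <- pos[pos >= segs$start[j] & pos < segs$end[j] - 1L]
      if (length(sel) < 2L) return(NULL)   # degenerate segment, skip
      d_mean <- if (segs$kind[j] == "imprinted") config$imprinted_diff_mean
                else config$nonimprinted_diff_mean
      d <- min(0.95, max(0.05, rnorm(1, d_mean, config$asm_diff_sd)))
      pat_high <- runif(1) < 0.5
      data.frame(chrom = ch, start = sel[1], end = sel[length(sel)] + 2L,
                 mu_pat = if (pat_high) 0.5 + d / 2 else 0.5 - d / 2,
                 mu_mat = if (pat_high) 0.5 - d / 2 else 0.5 + d / 2,
                 abs_diff = d,
                 class = ifelse(segs$kind[j] == "imprinted", "imprinted",
                                "non_imprinted"),
                 n_cpgs = length(sel))
    })
    asm_regions <- do.call(rbind, rows)
    if (is.null(asm_regions))
      asm_regions <- data.frame(chrom = character(0), start = integer(0),
                                end = integer(0), mu_pat = numeric(0),
                                mu_mat = numeric(0), abs_diff = numeric(0),
                                class = character(0), n_cpgs = integer(0))
    rownames(asm_regions) <- NULL
  }

  ## ---- DEGs and per-case DMRs -------------------------------------------
  genes <- ref$genes
  n_genes <- nrow(genes)
  deg_truth <- data.frame(gene_id = character(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          is_deg = logical(0), log2_fold_change = numeric(0),
                          coupled = logical(0), promoter_meth = numeric(0))
  dmrs <- data.frame(sample_id = character(0), chrom = character(0),
                     start = integer(0), end = integer(0), delta = numeric(0),
                     coupled_gene = character(0))
  if (n_genes > 0L) {
    n_deg <- round(config$deg_fraction * n_genes)
    deg_idx <- sort(sample.int(n_genes, n_deg))
    l2fc <- rep(0, n_genes)
    l2fc[deg_idx] <- sample(c(-1, 1), n_deg, TRUE) * runif(n_deg, 1, 3)
    n_coupled <- min(round(config$coupling_fraction * n_deg), config$n_dmrs)
    coupled_idx <- if (n_coupled > 0L) sort(sample(deg_idx, n_coupled))
                   else integer(0)
    deg_truth <- data.frame(
      gene_id = genes$gene_id, chrom = genes$chrom, start = genes$start,
      end = genes$end, is_deg = seq_len(n_genes) %in% deg_idx,
      log2_fold_change = l2fc,
      coupled = seq_len(n_genes) %in% coupled_idx,
      promoter_meth = prom_meth)

    case_ids <- if (config$n_cases > 0L)
      sprintf("case_%d", seq_len(config$n_cases)) else character(0)
    dmr_rows <- list()
    for (s in case_ids) {
      # one DMR adjacent to each coupled DEG (within the coupling distance)
      for (gi in coupled_idx) {
        g <- genes[gi, ]
        L <- ref$chrom_lengths[[g$chrom]]
        gap <- sample.int(max(1L, config$coupling_distance -
                                config$dmr_length), 1L) - 1L
        upstream_side <- runif(1) < 0.5
        st <- if (upstream_side) g$start - gap - config$dmr_length
              else g$end + gap
        st <- max(0L, min(L - config$dmr_length, st))
        dmr_rows[[length(dmr_rows) + 1L]] <- data.frame(
          sample_id = s, chrom = g$chrom, start = st,
          end = st + config$dmr_length,
          delta = sample(c(-1, 1), 1) *
            min(1, abs(rnorm(1, config$dmr_delta, 0.05))),
          coupled_gene = g$gene_id)
      }
      n_rand <- config$n_dmrs - n_coupled
      if (n_rand > 0L) {
        per <- split_count(n_rand, length(chroms))
        for (i in seq_along(chroms)) {
          if (per[i] == 0L) next
          pl <- place_intervals(per[i], config$dmr_length, chroms[i],
                                ref$chrom_lengths[[i]],
                                rbind(ref$gaps[, c("chrom", "start", "end")],
                                      segs[, c("chrom", "start", "end")]),
                                what = "DMR")
          pl$sample_id <- s
          pl$delta <- sample(c(-1, 1), per[i], TRUE) *
            pmin(1, abs(rnorm(per[i], config$dmr_delta, 0.05)))
          pl$coupled_gene <- NA_character_
          dmr_rows[[length(dmr_rows) + 1L]] <- pl[, c(
            "sample_id", "chrom", "start", "end", "delta", "coupled_gene")]
        }
      }
    }
    if (length(dmr_rows)) dmrs <- do.call(rbind, dmr_rows)
    rownames(dmrs) <- NULL
  }

  structure(list(het_snps = het_snps, asm_regions = asm_regions,
                 background_meth = background_meth, dmrs = dmrs,
                 deg_truth = deg_truth),
            class = "truth_set")
}

# fill het-SNP deserts inside the reserved ASM segments (plus a read-length
# shoulder) so every planted region is testable across its span; inserted
# SNPs avoid CpG dinucleotides so they do not erode the region's CpGs
ensure_segment_snps <- function(het_snps, ref, config, max_snp_gap = 150L) {
  segs <- ref$asm_segments
  if (!NROW(segs)) return(het_snps)
  extra <- list()
  for (j in seq_len(nrow(segs))) {
    ch <- segs$chrom[j]
    L <- ref$chrom_lengths[[ch]]
    lo <- max(0L, segs$start[j] - 100L)
    hi <- min(L - 1L, segs$end[j] + 100L)
    have <- sort(het_snps$pos[het_snps$chrom == ch &
                                het_snps$pos >= lo & het_snps$pos <= hi])
    anchors <- c(lo, have, hi)
    bases <- strsplit(ref$sequences[[ch]], "")[[1]]
    for (k in seq_len(length(anchors) - 1L)) {
      a <- anchors[k]; b <- anchors[k + 1L]
      while (b - a > max_snp_gap) {
        p <- a + sample.int(max_snp_gap, 1L)
        # step off CpG dinucleotides
        shift <- 0L
        while (shift < 5L && p + 1L < L &&
               ((bases[p + 1L] == "C" && bases[p + 2L] == "G") ||
                (p >= 1L && bases[p] == "C" && bases[p + 1L] == "G"))) {
          p <- p + 1L; shift <- shift + 1L
        }
        extra[[length(extra) + 1L]] <- data.frame(chrom = ch, pos = p)
        a <- p
      }
    }
  }
  if (!length(extra)) return(het_snps)
  add <- unique(do.call(rbind, extra))
  add <- add[!paste(add$chrom, add$pos) %in%
               paste(het_snps$chrom, het_snps$pos), , drop = FALSE]
  if (!nrow(add)) return(het_snps)
  pat <- vapply(seq_len(nrow(add)), function(i)
    substr(ref$sequences[[add$chrom[i]]], add$pos[i] + 1L, add$pos[i] + 1L),
    character(1))
  mat <- draw_mat_alleles(pat, config$confounded_fraction)
  sire_het <- runif(nrow(add)) < config$sire_het_fraction
  add <- data.frame(chrom = add$chrom, pos = add$pos, pat_base = pat,
                    mat_base = mat,
                    sire_genotype = ifelse(sire_het,
                                           paste(pat, mat, sep = "/"),
                                           paste(pat, pat, sep = "/")))
  out <- rbind(het_snps, add)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

# draw maternal alleles: `confounded` fraction forced to C/T or G/A pairs
draw_mat_alleles <- function(pat, confounded_fraction) {
  n <- length(pat)
  conf <- runif(n) < confounded_fraction
  mat <- character(n)
  conv_pair <- c(A = "G", G = "A", C = "T", T = "C")
  mat[conf] <- conv_pair[pat[conf]]
  # non-confounded: transversion partner, never completing C/T or G/A
  tv <- list(A = c("C", "T"), C = c("A", "G"), G = c("C", "T"), T = c("A", "G"))
  if (any(!conf))
    mat[!conf] <- vapply(pat[!conf],
                         function(b) sample(tv[[b]], 1L), character(1))
  mat
}

# logical: which 0-based positions fall in any [start, end) interval
pos_in_intervals <- function(pos, intervals) {
  if (length(pos) == 0L) return(logical(0))
  if (NROW(intervals) == 0L) return(rep(FALSE, length(pos)))
  o <- order(intervals$start)
  st <- intervals$start[o]; en <- intervals$end[o]
  idx <- findInterval(pos, st)
  idx > 0L & pos < en[pmax(idx, 1L)]
}

#' @export
print.truth_set <- function(x, ...) {
  cat("Planted truth set\n")
  cat(sprintf("  het SNPs: %s; ASM regions: %d (%d imprinted)\n",
              format(nrow(x$het_snps), big.mark = ","),
              nrow(x$asm_regions),
              sum(x$asm_regions$class == "imprinted")))
  cat(sprintf("  DMRs: %d across %d case sample(s); DEGs: %d (%d coupled)\n",
              nrow(x$dmrs), length(unique(x$dmrs$sample_id)),
              sum(x$deg_truth$is_deg), sum(x$deg_truth$coupled)))
  invisible(x)
}
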