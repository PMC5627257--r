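#' Generate a miniature reference genome bundle
#'
#' Builds the deterministic scaffold everything else is simulated on: per
#' chromosome a nucleotide sequence with depleted background CpGs, CpG
#' islands at regular spacing, engineered gene promoters spanning the
#' high/intermediate/low CpG-density classes, assembly gaps, segments
#' reserved for planted ASM regions, and a fully unmethylated lambda-like
#' spike-in sequence.
#'
#' Imprinted-gene annotations and the segments reserved for imprinted ASM
#' regions are confined to the first chromosome; segments for non-imprinted
#' ASM go to the remaining chromosome(s). On a miniature genome this keeps
#' the two classes separable by the >1 Mb distance-to-imprinted-gene rule.
#'
#' @param config an [sim_config()] object.
#' @return An object of class `ref_bundle`: a list with `chrom_names`,
#'   `chrom_lengths`, `sequences` (named character, or `NULL` when
#'   `config$generate_sequence` is `FALSE`), `cpg_sites` (0-based positions
#'   of the plus-strand C of every CpG, per chromosome), `cpg_islands`,
#'   `genes`, `imprinted_genes`, `gaps` and `asm_segments` interval data
#'   frames (0-based half-open), `lambda_sequence`, and the `config` echo.
#' @export
#' @examples
#' ref <- sim_reference(sim_config(seed = 1,
#'   chrom_lengths = c(chrA = 60000, chrB = 60000),
#'   n_genes = 6, n_imprinted_regions = 1, n_nonimprinted_regions = 1,
#'   island_spacing = 20000))
#' ref
sim_reference <- function(config) {
  stopifnot(inherits(config, "asm_sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)

  chroms <- names(config$chrom_lengths)
  lens <- as.integer(config$chrom_lengths)
  imprinted_chrom <- chroms[1L]

  ## ---- interval layout ---------------------------------------------------
  islands <- do.call(rbind, lapply(seq_along(chroms), function(i) {
    L <- lens[i]
    sp <- config$island_spacing
    il <- config$island_length
    anchors <- seq(sp %/% 2L, L - il, by = sp)
    if (length(anchors) == 0L)
      stop("configuration error: chromosome ", chroms[i],
           " too short to host a CpG island")
    jit <- as.integer(runif(length(anchors), -sp / 8, sp / 8))
    st <- pmax(0L, pmin(L - il, anchors + jit))
    data.frame(chrom = chroms[i], start = st, end = st + il)
  }))

  # imprinted ASM segments: whole islands on the first chromosome
  isl1 <- islands[islands$chrom == imprinted_chrom, ]
  if (config$n_imprinted_regions > nrow(isl1))
    stop("configuration error: ", config$n_imprinted_regions,
         " imprinted regions requested but only ", nrow(isl1),
         " islands available on ", imprinted_chrom)
  seg_imp <- if (config$n_imprinted_regions > 0L) {
    idx <- sort(sample.int(nrow(isl1), config$n_imprinted_regions))
    cbind(isl1[idx, ], kind = "imprinted")
  } else NULL

  # non-imprinted segments: CpG-retaining stretches away from the
  # imprinted chromosome (fall back to it only for single-chromosome genomes)
  host <- if (length(chroms) > 1L) chroms[-1L] else chroms
  occupied <- rbind(islands, if (!is.null(seg_imp)) seg_imp[, 1:3])
  seg_non <- NULL
  if (config$n_nonimprinted_regions > 0L) {
    per_host <- split_count(config$n_nonimprinted_regions, length(host))
    seg_non <- do.call(rbind, lapply(seq_along(host), function(i) {
      # clearance well above the region-chaining distance, so two planted
      # regions can never be merged into one detected region
      place_intervals(per_host[i], config$asm_region_length, host[i],
                      lens[match(host[i], chroms)], occupied,
                      margin = 2500L, what = "non-imprinted ASM segment")
    }))
    if (!is.null(seg_non) && nrow(seg_non)) {
      seg_non$kind <- "non_imprinted"
      occupied <- rbind(occupied, seg_non[, 1:3])
    }
  }
  asm_segments <- rbind(seg_imp, seg_non)
  if (is.null(asm_segments))
    asm_segments <- data.frame(chrom = character(0), start = integer(0),
                               end = integer(0), kind = character(0))

  gaps <- do.call(rbind, lapply(seq_along(chroms), function(i) {
    place_intervals(config$n_gaps_per_chrom, config$gap_length, chroms[i],
                    lens[i], occupied, margin = 200L, what = "assembly gap")
  }))
  if (is.null(gaps))
    gaps <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0))
  occupied <- rbind(occupied, gaps)

  genes <- place_genes(config, chroms, lens, occupied)
  imprinted_genes <- genes[genes$imprinted, c("chrom", "start", "end", "gene_id")]
  rownames(imprinted_genes) <- NULL

  ## ---- sequence ----------------------------------------------------------
  sequences <- NULL; cpg_sites <- NULL; lambda_sequence <- NULL
  if (config$generate_sequence) {
    sequences <- setNames(vector("character", length(chroms)), chroms)
    cpg_sites <- setNames(vector("list", length(chroms)), chroms)
    for (i in seq_along(chroms)) {
      b <- random_bases(lens[i], prob = c(0.29, 0.21, 0.21, 0.29))
      b <- deplete_cpgs(b, 0.85)
      b <- overwrite_segments(b, islands[islands$chrom == chroms[i], ],
                              style = "island")
      sn <- asm_segments[asm_segments$chrom == chroms[i] &
                           asm_segments$kind == "non_imprinted", ]
      b <- overwrite_segments(b, sn, style = "moderate")
      gi <- genes[genes$chrom == chroms[i], ]
      for (j in seq_len(nrow(gi))) {
        w <- promoter_window(gi$tss[j], gi$strand[j], 700L, 200L, lens[i])
        b <- overwrite_segments(b, data.frame(start = w[1], end = w[2]),
                                style = gi$promoter_target[j])
      }
      sequences[i] <- paste(b, collapse = "")
      cpg_sites[[i]] <- cpg_positions(sequences[i])
    }
    lambda_sequence <- paste(
      random_bases(config$lambda_length, prob = rep(0.25, 4)), collapse = "")
  }

  structure(list(
    chrom_names = chroms,
    chrom_lengths = setNames(lens, chroms),
    sequences = sequences,
    cpg_sites = cpg_sites,
    cpg_islands = islands,
    genes = genes,
    imprinted_genes = imprinted_genes,
    gaps = gaps,
    asm_segments = asm_segments,
    lambda_sequence = lambda_sequence,
    config = config
  ), class = "ref_bundle")
}

# split n as evenly as possible over k hosts
split_count <- function(n, k) {
  base <- n %/% k
  out <- rep(base, k)
  extra <- n - base * k
  if (extra > 0L) out[seq_len(extra)] <- out[seq_len(extra)] + 1L
  out
}

# rejection-place `n` intervals of length `len` on one chromosome, avoiding
# `occupied` (with a safety margin); error out when the chromosome is full
place_intervals <- function(n, len, chrom, chrom_len, occupied,
                            margin = 0L, what = "interval", max_tries = 2000L) {
  if (n == 0L) return(NULL)
  occ <- occupied[occupied$chrom == chrom, , drop = FALSE]
  placed_s <- integer(0)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      st <- sample.int(chrom_len - len + 1L, 1L) - 1L
      lo <- st - margin; hi <- st + len + margin
      clash <- (nrow(occ) && any(occ$start < hi & occ$end > lo)) ||
        (length(placed_s) && any(placed_s < hi & placed_s + len + margin > lo))
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok)
      stop("configuration error: could not place ", what, " #", k,
           " on ", chrom, " (chromosome too crowded)")
    placed_s <- c(placed_s, st)
    out[[k]] <- data.frame(chrom = chrom, start = st, end = st + len)
  }
  do.call(rbind, out)
}

place_genes <- function(config, chroms, lens, occupied) {
  empty <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), tss = integer(0),
                      tes = integer(0), promoter_target = character(0),
                      imprinted = logical(0))
  if (config$n_genes == 0L) return(empty)
  per <- split_count(config$n_genes, length(chroms))
  classes <- c("HCP", "ICP", "LCP")
  rows <- list(); gi <- 0L
  for (i in seq_along(chroms)) {
    occ <- occupied[occupied$chrom == chroms[i], , drop = FALSE]
    placed <- occ
    for (k in seq_len(per[i])) {
      glen <- as.integer(runif(1, config$gene_length_range[1],
                               config$gene_length_range[2] + 1))
      ok <- FALSE
      for (t in 1:2000) {
        st <- sample.int(lens[i] - glen - 1600L, 1L) - 1L + 800L
        lo <- st - 800L; hi <- st + glen + 800L
        if (!nrow(placed) || !any(placed$start < hi & placed$end > lo)) {
          ok <- TRUE; break
        }
      }
      if (!ok)
        stop("configuration error: could not place gene #", k, " on ",
             chroms[i], " (chromosome too crowded)")
      placed <- rbind(placed, data.frame(chrom = chroms[i], start = st,
                                         end = st + glen))
      gi <- gi + 1L
      strand <- sample(c("+", "-"), 1L)
      rows[[gi]] <- data.frame(
        gene_id = sprintf("gene_%03d", gi),
        chrom = chroms[i], start = st, end = st + glen, strand = strand,
        tss = if (strand == "+") st else st + glen - 1L,
        tes = if (strand == "+") st + glen - 1L else st,
        promoter_target = classes[(gi - 1L) %% 3L + 1L],
        imprinted = FALSE)
    }
  }
  genes <- do.call(rbind, rows)
  on1 <- which(genes$chrom == chroms[1L])
  genes$imprinted[head(on1, 2L)] <- TRUE
  rownames(genes) <- NULL
  genes
}

# strand-aware promoter window [-up, +down) around the TSS, clipped to the
# chromosome; returns c(start, end) 0-based half-open in genome coordinates
promoter_window <- function(tss, strand, up, down, chrom_len) {
  if (strand == "+") w <- c(tss - up, tss + down)
  else w <- c(tss - down + 1L, tss + up + 1L)
  c(max(0L, w[1]), min(chrom_len, w[2]))
}

# overwrite [start, end) stretches of a base vector with class-styled sequence
overwrite_segments <- function(bases, segs, style) {
  for (j in seq_len(NROW(segs))) {
    n <- segs$end[j] - segs$start[j]
    if (n <= 0L) next
    piece <- switch(style,
      island = random_bases(n, prob = c(0.2, 0.3, 0.3, 0.2)),
      HCP    = random_bases(n, prob = c(0.2, 0.3, 0.3, 0.2)),
      moderate = deplete_cpgs(random_bases(n, prob = rep(0.25, 4)), 0.45),
      ICP    = deplete_cpgs(random_bases(n, prob = rep(0.25, 4)), 0.45),
      LCP    = deplete_cpgs(random_bases(n, prob = c(0.3, 0.2, 0.2, 0.3)), 0.8),
      stop("unknown segment style: ", style))
    bases[(segs$start[j] + 1L):segs$end[j]] <- piece
  }
  bases
}

#' @export
print.ref_bundle <- function(x, ...) {
  cat("Reference bundle\n")
  cat(sprintf("  %d chromosome(s): %s\n", length(x$chrom_names),
              paste(sprintf("%s (%s bp)", x$chrom_names,
                            format(x$chrom_lengths, big.mark = ",")),
                    collapse = ", ")))
  ncpg <- if (is.null(x$cpg_sites)) NA_integer_ else
    sum(vapply(x$cpg_sites, length, integer(1)))
  cat(sprintf("  CpG sites: %s; islands: %d; genes: %d (%d imprinted); gaps: %d\n",
              ifelse(is.na(ncpg), "n/a (no sequence)",
                     format(ncpg, big.mark = ",")),
              nrow(x$cpg_islands), nrow(x$genes), nrow(x$imprinted_genes),
              nrow(x$gaps)))
  cat(sprintf("  reserved ASM segments: %d imprinted, %d non-imprinted\n",
              sum(x$asm_segments$kind == "imprinted"),
              sum(x$asm_segments$kind == "non_imprinted")))
  invisible(x)
}
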