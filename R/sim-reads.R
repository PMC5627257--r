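#' Simulate bisulfite read observations for one sample
#'
#' Draws uniformly placed read observations at the configured coverage and
#' emits, for every read, its SNP base calls and its C/T calls at covered
#' symmetric CpGs. Plus-strand reads report the plus-strand C of a CpG;
#' minus-strand reads report the minus-strand C (the base at position + 1),
#' keyed throughout by the plus-strand C position. Each call is Bernoulli in
#' the methylation level of the read's (latent) allele of origin, with
#' bisulfite conversion failure and read-end miscall bias applied. A
#' configured fraction of reads comes from the fully unmethylated lambda
#' spike-in; their cytosine calls (every covered C, not only CpG) are
#' recorded on the pseudo-chromosome `"lambda"`.
#'
#' SNP base calls are reported in plus-strand frame and carry the bisulfite
#' chemistry of the sequenced strand: a C allele read on the plus strand
#' appears as T when unmethylated, a G allele read on the minus strand as A.
#'
#' The allele of origin of every read is returned in a separate truth
#' channel (`allele_truth`) that no analysis function reads; the observation
#' channel (reads plus calls) is what the pipeline consumes.
#'
#' @param ref a [sim_reference()] bundle (with sequence).
#' @param truth the matching [plant_truth()] truth set.
#' @param config the [sim_config()] in use.
#' @param sample_id sample label, e.g. `"control_1"`.
#' @param group `"control"` or `"case"`; case samples additionally receive
#'   this sample's planted DMR shifts on both alleles.
#' @param seed integer seed for this sample's read stream (defaults to
#'   `config$seed`).
#' @return An object of class `read_set`: a list of data.tables `reads`
#'   (`read_id`, `chrom`, `start`, `end`, `strand`, `mate`), `cpg_calls`
#'   (`read_id`, `chrom`, `pos`, `call`, plus read coordinates for
#'   trimming), `snp_calls` (likewise with `base`), and `allele_truth`
#'   (`read_id`, `allele`), plus `sample_id`, `group` and a `trimmed` flag.
#' @export
simulate_reads <- function(ref, truth, config, sample_id,
                           group = c("control", "case"), seed = NULL) {
  stopifnot(inherits(ref, "ref_bundle"), inherits(truth, "truth_set"))
  if (is.null(ref$sequences))
    stop("simulate_reads needs a reference generated with sequence")
  group <- match.arg(group)
  set.seed(if (is.null(seed)) config$seed else seed)

  rl <- as.integer(config$read_length)
  cf <- config$conversion_failure
  reads_l <- list(); cpg_l <- list(); snp_l <- list(); next_id <- 0L

  for (ch in ref$chrom_names) {
    L <- ref$chrom_lengths[[ch]]
    if (L < rl) next
    n <- max(0L, as.integer(round(L * config$coverage_mean / rl)))
    if (n == 0L) next
    st <- sample.int(L - rl + 1L, n, replace = TRUE) - 1L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    mate <- sample(1:2, n, replace = TRUE)
    allele <- sample(c("pat", "mat"), n, replace = TRUE)
    rid <- next_id + seq_len(n); next_id <- next_id + n
    reads_l[[ch]] <- data.table::data.table(
      read_id = rid, chrom = ch, start = st, end = st + rl,
      strand = strand, mate = mate, allele = allele)

    lv <- allele_levels(ref, truth, config, ch, sample_id, group)
    pos <- ref$cpg_sites[[ch]]
    if (length(pos)) {
      plus <- strand == "+"
      fi <- findInterval(ifelse(plus, st - 1L, st - 2L), pos) + 1L
      li <- findInterval(ifelse(plus, st + rl - 1L, st + rl - 2L), pos)
      cnt <- pmax(0L, li - fi + 1L)
      if (sum(cnt)) {
        idx <- sequence(cnt, from = fi)
        k <- rep.int(seq_len(n), cnt)
        level <- ifelse(allele[k] == "pat", lv$pat[idx], lv$mat[idx])
        m <- sum(cnt)
        meth <- rbinom(m, 1L, level)
        cl <- rep("T", m)
        cl[meth == 1L] <- "C"
        cl[meth == 0L & runif(m) < cf] <- "C"
        covbase <- ifelse(plus[k], pos[idx], pos[idx] + 1L)
        off <- ifelse(plus[k], covbase - st[k], st[k] + rl - 1L - covbase)
        biased <- (mate[k] == 1L & off < 3L) |
                  (mate[k] == 2L & (off < 3L | off >= rl - 3L))
        flip <- biased & runif(m) < config$mbias_prob
        cl[flip] <- ifelse(cl[flip] == "C", "T", "C")
        cpg_l[[ch]] <- data.table::data.table(
          read_id = rid[k], chrom = ch, pos = pos[idx], call = cl,
          strand = strand[k], start = st[k], end = st[k] + rl)
      }
    }

    snps <- truth$het_snps[truth$het_snps$chrom == ch, ]
    if (nrow(snps)) {
      spos <- snps$pos
      fi <- findInterval(st - 1L, spos) + 1L
      li <- findInterval(st + rl - 1L, spos)
      cnt <- pmax(0L, li - fi + 1L)
      if (sum(cnt)) {
        idx <- sequence(cnt, from = fi)
        k <- rep.int(seq_len(n), cnt)
        b <- ifelse(allele[k] == "pat", snps$pat_base[idx], snps$mat_base[idx])
        m <- length(b)
        conv <- runif(m) >= cf
        b[strand[k] == "+" & b == "C" & conv] <- "T"
        b[strand[k] == "-" & b == "G" & conv] <- "A"
        snp_l[[ch]] <- data.table::data.table(
          read_id = rid[k], chrom = ch, pos = spos[idx], base = b,
          strand = strand[k], start = st[k], end = st[k] + rl)
      }
    }
  }

  reads <- data.table::rbindlist(reads_l)
  if (!nrow(reads))
    reads <- data.table::data.table(
      read_id = integer(0), chrom = character(0), start = integer(0),
      end = integer(0), strand = character(0), mate = integer(0),
      allele = character(0))
  n_lambda <- as.integer(round(nrow(reads) * config$spike_in_fraction))
  lam <- simulate_lambda_reads(ref, config, n_lambda, next_id, rl)
  allele_truth <- rbind(
    reads[, list(read_id, allele)],
    if (!is.null(lam)) lam$reads[, list(read_id, allele = NA_character_)])
  reads[, allele := NULL]
  reads <- data.table::rbindlist(list(reads,
    if (!is.null(lam)) lam$reads[, list(read_id, chrom, start, end, strand, mate)]))
  cpg_calls <- data.table::rbindlist(c(cpg_l, list(lam$calls)),
                                     use.names = TRUE, fill = TRUE)
  if (!nrow(cpg_calls))
    cpg_calls <- data.table::data.table(
      read_id = integer(0), chrom = character(0), pos = integer(0),
      call = character(0), strand = character(0), start = integer(0),
      end = integer(0))
  snp_calls <- data.table::rbindlist(snp_l)
  if (!nrow(snp_calls))
    snp_calls <- data.table::data.table(
      read_id = integer(0), chrom = character(0), pos = integer(0),
      base = character(0), strand = character(0), start = integer(0),
      end = integer(0))

  structure(list(reads = reads, cpg_calls = cpg_calls, snp_calls = snp_calls,
                 allele_truth = allele_truth, sample_id = sample_id,
                 group = group, read_length = rl, trimmed = FALSE),
            class = "read_set")
}

# per-CpG methylation level of each allele on one chromosome, for one sample
allele_levels <- function(ref, truth, config, ch, sample_id, group) {
  base <- truth$background_meth[[ch]]
  pat <- base; mat <- base
  pos <- ref$cpg_sites[[ch]]
  asm <- truth$asm_regions[truth$asm_regions$chrom == ch, ]
  for (j in seq_len(nrow(asm))) {
    sel <- pos >= asm$start[j] & pos < asm$end[j] - 1L
    pat[sel] <- asm$mu_pat[j]; mat[sel] <- asm$mu_mat[j]
  }
  if (group == "case") {
    dmr <- truth$dmrs[truth$dmrs$chrom == ch &
                        truth$dmrs$sample_id == sample_id, ]
    for (j in seq_len(nrow(dmr))) {
      sel <- pos >= dmr$start[j] & pos < dmr$end[j]
      pat[sel] <- clamp01(pat[sel] + dmr$delta[j])
      mat[sel] <- clamp01(mat[sel] + dmr$delta[j])
    }
  }
  list(pat = pat, mat = mat)
}

# unmethylated spike-in reads; cytosine calls on both strands of "lambda"
simulate_lambda_reads <- function(ref, config, n, next_id, rl) {
  if (n <= 0L || is.null(ref$lambda_sequence)) return(NULL)
  L <- nchar(ref$lambda_sequence)
  if (L < rl) return(NULL)
  bases <- strsplit(ref$lambda_sequence, "")[[1]]
  posC <- which(bases == "C") - 1L   # plus-strand cytosines
  posG <- which(bases == "G") - 1L   # minus-strand cytosines
  st <- sample.int(L - rl + 1L, n, replace = TRUE) - 1L
  strand <- sample(c("+", "-"), n, replace = TRUE)
  mate <- sample(1:2, n, replace = TRUE)
  rid <- next_id + seq_len(n)
  reads <- data.table::data.table(read_id = rid, chrom = "lambda",
                                  start = st, end = st + rl,
                                  strand = strand, mate = mate)
  call_rows <- lapply(seq_len(n), function(i) NULL)
  plus <- strand == "+"
  mk <- function(sel, pp) {
    if (!any(sel)) return(NULL)
    fi <- findInterval(st[sel] - 1L, pp) + 1L
    li <- findInterval(st[sel] + rl - 1L, pp)
    cnt <- pmax(0L, li - fi + 1L)
    if (!sum(cnt)) return(NULL)
    idx <- sequence(cnt, from = fi)
    k <- rep.int(which(sel), cnt)
    data.table::data.table(read_id = rid[k], chrom = "lambda", pos = pp[idx],
                           strand = strand[k], start = st[k], end = st[k] + rl)
  }
  calls <- data.table::rbindlist(list(mk(plus, posC), mk(!plus, posG)))
  if (nrow(calls)) {
    calls[, call := ifelse(runif(.N) < config$conversion_failure, "C", "T")]
  } else calls <- NULL
  list(reads = reads, calls = calls)
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("Read set '%s' (%s): %s reads (%s spike-in), %s CpG calls, %s SNP calls%s\n",
              x$sample_id, x$group,
              format(nrow(x$reads), big.mark = ","),
              format(sum(x$reads$chrom == "lambda"), big.mark = ","),
              format(nrow(x$cpg_calls), big.mark = ","),
              format(nrow(x$snp_calls), big.mark = ","),
              if (x$trimmed) " [trimmed]" else ""))
  invisible(x)
}

#' Simulate a full dataset: reference, truth, reads and expression
#'
#' Convenience wrapper running every generator stage for all configured
#' samples. Per-sample read streams use seeds `config$seed + 100 + i` so the
#' whole dataset is a pure function of the configuration.
#'
#' @param config an [sim_config()] object.
#' @param reads if `FALSE`, skip read simulation (intervals/expression only).
#' @param expression if `FALSE`, skip the expression table.
#' @return A list of class `asm_dataset` with `ref`, `truth`, `read_sets`
#'   (named by sample), and `expression` (gene x sample count matrix).
#' @export
simulate_dataset <- function(config, reads = TRUE, expression = TRUE) {
  ref <- sim_reference(config)
  truth <- plant_truth(ref, config)
  samples <- c(if (config$n_controls > 0)
                 sprintf("control_%d", seq_len(config$n_controls)),
               if (config$n_cases > 0)
                 sprintf("case_%d", seq_len(config$n_cases)))
  groups <- rep(c("control", "case"), c(config$n_controls, config$n_cases))
  read_sets <- NULL
  if (reads && config$generate_sequence) {
    read_sets <- lapply(seq_along(samples), function(i)
      simulate_reads(ref, truth, config, samples[i], groups[i],
                     seed = config$seed + 100L + i))
    names(read_sets) <- samples
  }
  expr <- if (expression && nrow(ref$genes))
    emit_expression(truth, ref, config) else NULL
  structure(list(ref = ref, truth = truth, read_sets = read_sets,
                 expression = expr, samples = samples, groups = groups),
            class = "asm_dataset")
}

#' @export
print.asm_dataset <- function(x, ...) {
  cat("Simulated F1-hybrid dataset\n")
  print(x$ref$config)
  invisible(x)
}
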