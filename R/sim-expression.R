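#' Emit a gene-by-sample expression count matrix
#'
#' Negative-binomial counts around per-gene baselines. Genes whose engineered
#' promoter class is HCP or ICP are coupled negatively to their planted
#' promoter methylation (expression drops by `expr_coupling_strength` log2
#' units per unit of methylation); LCP-promoter genes are left uncoupled,
#' mirroring the usual absence of methylation-expression correlation at low
#' CpG-density promoters. DEG truth genes are shifted by their planted log2
#' fold-change in case samples.
#'
#' @param truth a [plant_truth()] truth set.
#' @param ref the matching [sim_reference()] bundle.
#' @param config the [sim_config()] in use.
#' @param seed seed for the count draws (default `config$seed + 2`).
#' @return Integer matrix, genes in rows (named by `gene_id`), samples in
#'   columns (`control_1..n`, `case_1..n`).
#' @export
emit_expression <- function(truth, ref, config, seed = NULL) {
  genes <- ref$genes
  if (nrow(genes) == 0L) stop("gene list is empty")
  set.seed(if (is.null(seed)) config$seed + 2L else seed)

  n <- nrow(genes)
  base <- exp(rnorm(n, log(200), 1))
  coupled_class <- genes$promoter_target %in% c("HCP", "ICP")
  m <- truth$deg_truth$promoter_meth
  m[is.na(m)] <- 0.5
  # silencing: a methylated HCP/ICP promoter makes the gene more likely to
  # be (near-)silent; LCP genes go silent at the flat background rate
  p_zero <- ifelse(coupled_class,
                   clamp01(2 * config$expr_zero_fraction * m),
                   config$expr_zero_fraction)
  zero <- runif(n) < p_zero
  base[zero] <- runif(sum(zero), 0, 0.5)
  base[coupled_class] <- base[coupled_class] *
    2^(-config$expr_coupling_strength * (m[coupled_class] - 0.5))

  samples <- c(if (config$n_controls > 0)
                 sprintf("control_%d", seq_len(config$n_controls)),
               if (config$n_cases > 0)
                 sprintf("case_%d", seq_len(config$n_cases)))
  is_case <- grepl("^case_", samples)
  counts <- matrix(0L, n, length(samples),
                   dimnames = list(genes$gene_id, samples))
  fc <- 2^truth$deg_truth$log2_fold_change
  for (j in seq_along(samples)) {
    mu <- if (is_case[j]) base * fc else base
    counts[, j] <- rnbinom(n, mu = mu, size = config$nb_size)
  }
  counts
}

#' Counts-per-million normalization
#'
#' @param counts gene x sample count matrix.
#' @return matrix of the same shape with each column scaled to sum to 1e6.
#' @export
cpm <- function(counts) {
  sweep(counts, 2, pmax(colSums(counts), 1), "/") * 1e6
}
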