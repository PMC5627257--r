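#' Simulation configuration for the F1-hybrid WGBS emulator
#'
#' Collects every tunable of the synthetic-data generator into a validated
#' configuration object. The defaults describe the study conditions the rest
#' of the package is exercised under: a miniature two-chromosome diploid
#' genome sequenced to ~26x mean coverage with 100 bp reads, a bisulfite
#' conversion failure rate of 0.69% (conversion rate 99.31%), a 0.5%
#' unmethylated lambda-like spike-in, and four control plus four case
#' individuals.
#'
#' @param seed integer seed; all downstream generator stages derive their
#'   random streams from it, so identical configurations reproduce identical
#'   datasets byte for byte.
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param generate_sequence if `FALSE`, only interval annotations (genes,
#'   islands, gaps) are generated; no nucleotide sequence, SNPs or methylation
#'   truth. Useful for interval-level association studies at larger genome
#'   sizes where sequence is irrelevant.
#' @param coverage_mean mean read coverage per base (reads of `read_length`).
#' @param read_length read length in bp (single observations; mates 1 and 2
#'   are simulated as independent reads).
#' @param conversion_failure probability that an unmethylated (converted)
#'   cytosine still reads as "C".
#' @param mbias_prob extra per-position miscall probability applied at the
#'   first 3 positions of mate-1 reads and the first and last 3 positions of
#'   mate-2 reads (read-end methylation bias).
#' @param n_controls,n_cases number of control / case individuals.
#' @param spike_in_fraction fraction of reads drawn from the fully
#'   unmethylated lambda spike-in sequence.
#' @param lambda_length length (bp) of the synthetic spike-in sequence.
#' @param snp_rate per-bp probability of a heterozygous SNP between the
#'   parental haplotypes.
#' @param sire_het_fraction fraction of heterozygous SNPs at which the sire
#'   itself is heterozygous (uninformative for parental assignment).
#' @param confounded_fraction fraction of het SNPs forced to be C/T or G/A,
#'   i.e. bisulfite-confounded on one strand.
#' @param island_spacing,island_length spacing and length (bp) of CpG islands.
#' @param n_genes total number of genes (split evenly across chromosomes).
#' @param gene_length_range min/max gene body length (bp).
#' @param n_gaps_per_chrom,gap_length assembly-gap count per chromosome and
#'   gap length (bp).
#' @param n_imprinted_regions,n_nonimprinted_regions numbers of planted ASM
#'   regions of each class. Imprinted regions sit on CpG islands of the first
#'   chromosome (which also hosts the annotated imprinted genes);
#'   non-imprinted regions sit on moderately CpG-dense segments of the other
#'   chromosome(s), so the two classes are separable by the 1 Mb distance
#'   rule even on a miniature genome.
#' @param imprinted_diff_mean,nonimprinted_diff_mean,asm_diff_sd mean and SD
#'   of the planted between-allele methylation difference per class.
#' @param asm_region_length length (bp) of non-imprinted ASM segments.
#' @param n_dmrs,dmr_length,dmr_delta DMR count per case sample, DMR length
#'   (bp) and absolute methylation shift of case samples within a DMR.
#' @param deg_fraction fraction of genes that are differentially expressed in
#'   case samples.
#' @param coupling_fraction fraction of DEGs given a DMR within
#'   `coupling_distance` in every case sample.
#' @param coupling_distance bp distance within which a coupled DEG's DMR is
#'   placed.
#' @param expr_zero_fraction fraction of genes with near-zero expression.
#' @param expr_coupling_strength log2 expression units lost per unit of
#'   promoter methylation for genes with high/intermediate CpG-density
#'   promoters (negative methylation-expression coupling).
#' @param nb_size negative-binomial size (dispersion) of expression counts.
#'
#' @return An object of class `asm_sim_config` (a validated named list).
#' @seealso [sim_reference()], [plant_truth()], [simulate_reads()],
#'   [emit_expression()], [simulate_dataset()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, chrom_lengths = c(chrA = 60000, chrB = 60000))
#' cfg
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 500000L, chr2 = 500000L),
                       generate_sequence = TRUE,
                       coverage_mean = 26,
                       read_length = 100L,
                       conversion_failure = 0.0069,
                       mbias_prob = 0.05,
                       n_controls = 4L,
                       n_cases = 4L,
                       spike_in_fraction = 0.005,
                       lambda_length = 20000L,
                       snp_rate = 0.01,
                       sire_het_fraction = 0.05,
                       confounded_fraction = 0.5,
                       island_spacing = 50000L,
                       island_length = 1500L,
                       n_genes = 90L,
                       gene_length_range = c(2000L, 4000L),
                       n_gaps_per_chrom = 2L,
                       gap_length = 5000L,
                       n_imprinted_regions = 6L,
                       n_nonimprinted_regions = 10L,
                       imprinted_diff_mean = 0.73,
                       nonimprinted_diff_mean = 0.51,
                       asm_diff_sd = 0.05,
                       asm_region_length = 1500L,
                       n_dmrs = 8L,
                       dmr_length = 1500L,
                       dmr_delta = 0.3,
                       deg_fraction = 0.4,
                       coupling_fraction = 0.3,
                       coupling_distance = 5000L,
                       expr_zero_fraction = 0.2,
                       expr_coupling_strength = 8,
                       nb_size = 10) {
  cfg <- as.list(environment())
  class(cfg) <- "asm_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1L)
  if (is.null(names(cfg$chrom_lengths)) || any(names(cfg$chrom_lengths) == ""))
    stop("chrom_lengths must be a named vector")
  if (any(cfg$chrom_lengths < 1))
    stop("chromosome lengths must be positive")
  probs <- c(conversion_failure = cfg$conversion_failure,
             mbias_prob = cfg$mbias_prob,
             spike_in_fraction = cfg$spike_in_fraction,
             snp_rate = cfg$snp_rate,
             sire_het_fraction = cfg$sire_het_fraction,
             confounded_fraction = cfg$confounded_fraction,
             deg_fraction = cfg$deg_fraction,
             coupling_fraction = cfg$coupling_fraction,
             expr_zero_fraction = cfg$expr_zero_fraction)
  bad <- probs < 0 | probs > 1
  if (any(bad))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[bad], collapse = ", "))
  if (cfg$coverage_mean <= 0) stop("coverage_mean must be > 0")
  if (cfg$read_length < 6) stop("read_length must be at least 6 bp")
  if (cfg$n_controls < 1) stop("need at least one control sample")
  if (cfg$dmr_delta < 0 || cfg$dmr_delta > 1)
    stop("dmr_delta must lie in [0, 1]")
  invisible(cfg)
}

#' @export
print.asm_sim_config <- function(x, ...) {
  cat("F1-hybrid WGBS simulation configuration\n")
  cat(sprintf("  genome: %d chromosome(s), %s bp total%s\n",
              length(x$chrom_lengths),
              format(sum(x$chrom_lengths), big.mark = ","),
              if (x$generate_sequence) "" else " (intervals only)"))
  cat(sprintf("  samples: %d controls + %d cases, %.0fx coverage, %d bp reads\n",
              x$n_controls, x$n_cases, x$coverage_mean, x$read_length))
  cat(sprintf("  conversion failure %.2f%%, spike-in %.2f%%, het SNP rate 1/%.0f bp\n",
              100 * x$conversion_failure, 100 * x$spike_in_fraction,
              1 / max(x$snp_rate, 1e-12)))
  cat(sprintf("  planted ASM: %d imprinted (diff ~%.2f) + %d non-imprinted (diff ~%.2f)\n",
              x$n_imprinted_regions, x$imprinted_diff_mean,
              x$n_nonimprinted_regions, x$nonimprinted_diff_mean))
  cat(sprintf("  DMRs/case: %d x %d bp (|delta| %.2f); DEG fraction %.2f, coupling %.2f\n",
              x$n_dmrs, x$dmr_length, x$dmr_delta, x$deg_fraction,
              x$coupling_fraction))
  invisible(x)
}
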