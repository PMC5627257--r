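# shared fixtures and independent oracles, built in code at test time

# small genome that still hosts islands, genes, gaps and one region per class
tiny_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed,
         chrom_lengths = c(chrA = 120000L, chrB = 120000L),
         island_spacing = 30000L,
         n_genes = 12L,
         n_imprinted_regions = 2L, n_nonimprinted_regions = 2L,
         n_dmrs = 3L, n_gaps_per_chrom = 1L),
    list(...))
  do.call(sim_config, args)
}

# full study-scale configuration (the package defaults)
study_config <- function(seed = 1L, ...) sim_config(seed = seed, ...)

# interval-only geometry used for the DMR-DEG association studies
assoc_config <- function(seed = 1L, coupling_fraction = 0.3, ...) {
  sim_config(seed = seed,
             chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
             generate_sequence = FALSE,
             n_genes = 200L, n_dmrs = 60L,
             coupling_fraction = coupling_fraction,
             island_spacing = 500000L, n_gaps_per_chrom = 4L,
             ...)
}

sim_controls <- function(cfg, ref, truth, n = cfg$n_controls) {
  lapply(seq_len(n), function(i)
    simulate_reads(ref, truth, cfg, sprintf("control_%d", i), "control",
                   seed = cfg$seed + 100L + i))
}

# hand-built read_set for unit tests of trimming / pileup / assignment.
# calls are given as data.frames with read-level coordinates attached.
manual_read_set <- function(reads, cpg_calls = NULL, snp_calls = NULL) {
  reads <- data.table::as.data.table(reads)
  fill <- function(df, value_col) {
    if (is.null(df)) {
      out <- data.table::data.table(read_id = integer(0),
                                    chrom = character(0), pos = integer(0),
                                    strand = character(0), start = integer(0),
                                    end = integer(0))
      out[[value_col]] <- character(0)
      return(out)
    }
    df <- data.table::as.data.table(df)
    df[reads, on = "read_id",
       c("chrom", "strand", "start", "end") :=
         list(i.chrom, i.strand, i.start, i.end)]
    df
  }
  structure(list(reads = reads,
                 cpg_calls = fill(cpg_calls, "call"),
                 snp_calls = fill(snp_calls, "base"),
                 allele_truth = NULL, sample_id = "manual",
                 group = "control",
                 read_length = if (nrow(reads)) reads$end[1] - reads$start[1]
                               else NA_integer_,
                 trimmed = FALSE),
            class = "read_set")
}

# minimal reference with explicitly chosen CpG positions (for pileup tests)
manual_ref <- function(cpg_sites, chrom_lengths = NULL) {
  chroms <- names(cpg_sites)
  if (is.null(chrom_lengths))
    chrom_lengths <- setNames(rep(1e6L, length(chroms)), chroms)
  structure(list(chrom_names = chroms, chrom_lengths = chrom_lengths,
                 sequences = NULL, cpg_sites = cpg_sites,
                 cpg_islands = data.frame(chrom = character(0),
                                          start = integer(0),
                                          end = integer(0)),
                 genes = NULL, imprinted_genes = NULL, gaps = NULL,
                 asm_segments = NULL, lambda_sequence = NULL, config = NULL),
            class = "ref_bundle")
}

# brute-force pairwise interval overlap (any >= 1 bp, half-open)
any_overlap <- function(a, b) {
  any(vapply(seq_len(nrow(a)), function(i)
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i]),
    logical(1)))
}

# brute-force overlap oracle: which DEGs have any DMR within `ext` bp
brute_associated <- function(degs, dmrs, ext) {
  hit <- vapply(seq_len(nrow(degs)), function(i) {
    any(dmrs$chrom == degs$chrom[i] &
          dmrs$start < degs$end[i] + ext &
          dmrs$end > degs$start[i] - ext)
  }, logical(1))
  sort(degs$gene_id[hit])
}
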