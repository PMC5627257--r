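# File-format boundary. Internally everything is 0-based half-open;
# 1-based coordinates appear only inside VCF records.

#' Write the reference (and spike-in) sequences as FASTA
#'
#' @param ref a `ref_bundle` with sequences.
#' @param path output FASTA path.
#' @export
write_reference_fasta <- function(ref, path) {
  if (is.null(ref$sequences)) stop("reference has no sequence")
  seqs <- c(ref$sequences, lambda = ref$lambda_sequence)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write intervals as BED6
#'
#' 0-based half-open, matching the internal convention.
#'
#' @param df interval data frame (`chrom`, `start`, `end`; optional `name`,
#'   `score`, `strand` columns are used when present).
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  check_interval_df(df)
  out <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = if ("name" %in% names(df)) df$name else ".",
                    score = if ("score" %in% names(df)) df$score else 0L,
                    strand = if ("strand" %in% names(df)) df$strand else ".")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into the internal interval convention
#'
#' Uses `rtracklayer` when available (the canonical BED reader), falling
#' back to a plain whitespace table read of the first six columns.
#'
#' @param path BED path.
#' @return data frame `chrom`, `start`, `end` (0-based half-open) plus
#'   `name`/`score`/`strand` when present.
#' @export
read_bed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr))
    md <- S4Vectors::mcols(gr)
    for (col in intersect(c("name", "score"), names(md)))
      out[[col]] <- md[[col]]
    st <- as.character(GenomicRanges::strand(gr))
    if (any(st != "*")) out$strand <- st
    return(out)
  }
  x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(x)[seq_len(min(6L, ncol(x)))] <-
    c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(6L, ncol(x)))]
  x
}

#' Write heterozygous SNPs as a minimal VCF v4.2
#'
#' REF is the paternal allele, ALT the maternal allele; one sample column
#' carries the sire genotype (`0/0` when the sire is homozygous paternal,
#' `0/1` when heterozygous). Positions are converted to 1-based.
#'
#' @param het_snps SNP data frame (see [plant_truth()]).
#' @param path output path.
#' @param sire_id sample name for the sire column.
#' @export
write_snps_vcf <- function(het_snps, path, sire_id = "SIRE") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=asmscout",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      sire_id)), con)
  if (nrow(het_snps)) {
    al <- strsplit(het_snps$sire_genotype, "/", fixed = TRUE)
    hom <- vapply(al, function(a) a[1] == a[2], logical(1))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                       het_snps$chrom, het_snps$pos + 1L, het_snps$pat_base,
                       het_snps$mat_base, ifelse(hom, "0/0", "0/1")), con)
  }
  invisible(path)
}

#' Read heterozygous SNPs from a VCF written by [write_snps_vcf()]
#'
#' Requires the `vcfR` package.
#'
#' @param path VCF path.
#' @return SNP data frame in the internal convention (0-based `pos`).
#' @export
read_snps_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_snps_vcf requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  pat <- as.character(fix[, "REF"]); mat <- as.character(fix[, "ALT"])
  sire <- ifelse(gt[, 1] %in% c("0/0", "0|0"),
                 paste(pat, pat, sep = "/"), paste(pat, mat, sep = "/"))
  data.frame(chrom = as.character(fix[, "CHROM"]),
             pos = as.integer(fix[, "POS"]) - 1L,
             pat_base = pat, mat_base = mat, sire_genotype = unname(sire))
}

#' Write read observations as TSV
#'
#' One line per read: `chrom start end strand mate snp_calls cpg_calls`,
#' with calls packed as `pos:base` pairs separated by `;`. The latent
#' allele-of-origin truth channel is deliberately not written.
#'
#' @param rs a `read_set`.
#' @param path output path.
#' @export
write_reads_tsv <- function(rs, path) {
  stopifnot(inherits(rs, "read_set"))
  pack <- function(calls, val_col) {
    if (!nrow(calls)) return(data.table::data.table(read_id = integer(0),
                                                    packed = character(0)))
    calls[, list(packed = paste(paste0(pos, ":", get(val_col)),
                                collapse = ";")), by = read_id]
  }
  reads <- data.table::copy(rs$reads)
  sp <- pack(rs$snp_calls, "base")
  cp <- pack(rs$cpg_calls, "call")
  reads[sp, snp_calls := i.packed, on = "read_id"]
  reads[cp, cpg_calls := i.packed, on = "read_id"]
  reads[is.na(snp_calls), snp_calls := "."]
  reads[is.na(cpg_calls), cpg_calls := "."]
  data.table::fwrite(
    reads[, list(chrom, start, end, strand, mate, snp_calls, cpg_calls)],
    path, sep = "\t")
  invisible(path)
}

#' Read a read-observation TSV back into a `read_set`
#'
#' @param path TSV written by [write_reads_tsv()].
#' @param sample_id,group labels for the reconstructed set.
#' @return a `read_set` (without the allele truth channel).
#' @export
read_reads_tsv <- function(path, sample_id = "sample", group = "control") {
  x <- data.table::fread(path, sep = "\t")
  x[, read_id := .I]
  unpack <- function(col, val_name) {
    has <- which(x[[col]] != "." & !is.na(x[[col]]))
    if (!length(has))
      return(data.table::data.table(read_id = integer(0), chrom = character(0),
                                    pos = integer(0), val = character(0),
                                    strand = character(0), start = integer(0),
                                    end = integer(0)))
    parts <- strsplit(x[[col]][has], ";", fixed = TRUE)
    n <- lengths(parts)
    flat <- unlist(parts, use.names = FALSE)
    kv <- data.table::tstrsplit(flat, ":", fixed = TRUE)
    idx <- rep.int(has, n)
    out <- data.table::data.table(
      read_id = x$read_id[idx], chrom = x$chrom[idx],
      pos = as.integer(kv[[1]]), val = kv[[2]],
      strand = x$strand[idx], start = x$start[idx], end = x$end[idx])
    data.table::setnames(out, "val", val_name)
    out
  }
  structure(list(
    reads = x[, list(read_id, chrom, start, end, strand, mate)],
    cpg_calls = unpack("cpg_calls", "call"),
    snp_calls = unpack("snp_calls", "base"),
    allele_truth = NULL, sample_id = sample_id, group = group,
    read_length = if (nrow(x)) as.integer(x$end[1] - x$start[1]) else NA_integer_,
    trimmed = FALSE), class = "read_set")
}

#' Write a per-CpG table as bedGraph-compatible TSV
#'
#' Columns `chrom`, `start`, `end` (the CpG dinucleotide, 0-based
#' half-open), `level`, `n_C`, `n_T`.
#'
#' @param tab per-CpG table from [pileup_cpgs()].
#' @param path output path.
#' @export
write_cpg_table <- function(tab, path) {
  out <- data.frame(chrom = tab$chrom, start = tab$pos, end = tab$pos + 2L,
                    level = tab$level, n_C = tab$n_C, n_T = tab$n_T)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a per-CpG TSV written by [write_cpg_table()]
#' @param path input path.
#' @return per-CpG data frame (`chrom`, `pos`, `n_C`, `n_T`, `level`).
#' @export
read_cpg_table <- function(path) {
  x <- data.table::fread(path, sep = "\t")
  out <- data.frame(chrom = x$chrom, pos = x$start, n_C = x$n_C, n_T = x$n_T,
                    level = x$level)
  out
}

#' Echo a simulation configuration (with its seed) to JSON
#'
#' @param config an `asm_sim_config`.
#' @param path output path.
#' @export
write_config_json <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
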