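---
title: "Detecting allele-specific methylation and its transcriptome context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting allele-specific methylation and its transcriptome context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmscout)
```

## The problem

In an F1 hybrid of two divergent parental lines, heterozygous SNPs make the
two parental haplotypes distinguishable in sequencing reads. Whole-genome
bisulfite sequencing (WGBS) reads that overlap such a SNP can be assigned to
the paternal or maternal allele, and the methylation state of each allele
can then be compared CpG by CpG. A locus where the two alleles carry
systematically different methylation is an allele-specific methylation (ASM)
region; ASM at known imprinted loci reflects genomic imprinting, while ASM
far from any imprinted gene usually reflects cis-acting sequence
polymorphism.

`asmscout` implements this detection procedure end to end, together with two
companion analyses: a spatial association test between differentially
methylated regions (DMRs) and differentially expressed genes (DEGs) built on
a chromosome-restricted interval-shuffling null, and genome-wide
methylome-transcriptome profiling (methylation-level histograms, metagene
profiles by expression group, promoter CpG-density classes, and
promoter/gene-body methylation-expression correlations). Because the real
data this kind of study uses are large and external, the package ships a
synthetic-data generator that emulates the full study design at desk scale
with known planted truth, so every stage is testable offline.

## The detection model

**Per-CpG methylation.** Bisulfite conversion leaves methylated cytosines as
C and converts unmethylated ones to T. After alignment, the level of a CpG
is the ratio of C-calls to total (C+T) calls, pooling the plus-strand C and
the minus-strand C of the symmetric CpG into one record keyed by the
plus-strand position. Reads are first trimmed: calls in the first 3 and
last 2 bases of each read are discarded because read ends carry a
methylation bias introduced during library preparation. CpGs whose
dinucleotide overlaps a heterozygous SNP are excluded, since their context
differs between alleles, and a genome-wide table conventionally keeps CpGs
covered by at least 5 reads. An unmethylated lambda spike-in provides the
bisulfite conversion-rate estimate T/(C+T) over its cytosine calls.

**Parental-origin assignment.** Every informative SNP a read overlaps casts
a vote: the base matching the sire's homozygous allele is paternal, the
alternative parental allele maternal. Two classes of SNP are uninformative
and skipped: SNPs where the sire is itself heterozygous, and SNPs that
bisulfite chemistry confounds on the read's strand (C/T alleles on a
plus-strand read, G/A on a minus-strand read, since conversion itself turns
C into T). Reads with conflicting or no informative votes are ambiguous and
dropped rather than fractionally assigned.

**Testing and FDR.** Allelic reads are pooled across the control
individuals; a CpG with at least 4x coverage of *each* allele is tested
with a two-sided Fisher exact test on its 2x2 allele-by-call table, and
CpGs with p < 0.01 become ASM candidates. The false discovery rate is
estimated by permutation: every assigned read's allele label is replaced by
a fair coin flip, the identical pooling/filter/test path is rerun, and the
FDR is the ratio of randomized to observed candidate counts (averaged over
replicates when more than one permutation is run; the default is one).

**Clustering into regions.** Candidate CpGs on a chromosome are chained
when separated by at most `max_gap` bp; a chain becomes a region when it
contains at least `min_cluster_size` candidates and candidates make up at
least `min_purity` of the tested CpGs in its span. Two defaults deserve
explanation:

* `max_gap = 1000`. Candidates can only exist where reads carry an
  informative SNP, so a contiguous ASM region is interrupted by SNP-poor
  stretches in which no CpG is testable. The chaining distance has to
  bridge those stretches; at the SNP densities this pipeline targets they
  reach several hundred bp. With the observed null candidate rate (well
  under 1% of tested CpGs), chaining across 1 kb still cannot assemble five
  scattered false positives into a region.
* `edge_gap = 250`. A lone false-positive candidate sitting up to 1 kb
  outside a true region would otherwise be chained in and stretch the
  region boundary. Genuine region edges are candidate-dense, so terminal
  candidates separated from the rest of the chain by more than 250 bp are
  trimmed off.

Regions within 1 Mb of a known imprinted gene are classified `imprinted`,
all others `non_imprinted`; per-region statistics (size, CpG density,
per-allele means, |paternal - maternal| difference, island overlap) and
per-class summaries come from `characterize_regions()`.

## The association test

A DEG counts as associated with a DMR when the DMR overlaps the gene
interval extended by 5 kb (or 20 kb) on both sides, overlap meaning at
least 1 bp of the half-open intervals. To ask whether the observed number
of associated DEGs exceeds chance, each DMR is re-placed uniformly at
random on its own chromosome 1000 times, preserving its length and
excluding assembly gaps (rejection sampling, 10,000 tries per interval
before a placement error). The mean associated count over shuffles is the
expected count E, and the observed count O is tested with a two-cell
goodness-of-fit chi-square on {associated, not associated} with one degree
of freedom:

\[ \chi^2 = \frac{(O-E)^2}{E} + \frac{(O-E)^2}{N-E}. \]

When E is degenerate (0 or N) the chi-square is undefined and the exact
permutation tail probability (fraction of shuffles with a count at least O)
is reported instead, flagged in the result's `method` field. Shuffled
intervals may overlap each other; nothing in the procedure forbids it.

Supporting helpers cover the remaining quantities of this analysis family:
the associated-DEG percentage, pairwise DMR-set intersections, the mean
methylation difference over the strand-aware TSS window (-1.5 kb, +500 bp)
of genes with at least 2-fold expression change, and a pooled-variance
two-sample t test from published group summaries (mean, SD, n). The
`scan_dmrs_naive()` window scanner is deliberately crude plumbing for
producing DMR-like intervals from per-CpG tables when no dedicated DMR
caller is in the loop; it is not a smoothing-based method and no validation
claim rests on it.

## Methylome-transcriptome profiling

Genes are split into five expression groups: group 1 below a normalized
abundance floor (default 0.1, on counts-per-million), groups 2-5 the
quartiles of the rest, ranked with stable tie-breaking so the grouping is
invariant under monotone transforms and input order. The metagene profile
averages per-CpG levels in 50 bp bins over a 3 kb flank on each side and
100 length-scaled bins over the gene body, strand-oriented, with empty bins
reported as missing rather than zero.

Promoters are classified by CpG density over sliding 500 bp sub-windows
(step 50 bp) of the -700/+200 window around the TSS, using the CpG
observed/expected ratio \(n_{CpG} \cdot L / (n_C \cdot n_G)\) (defined as 0
when the window lacks C or G) and GC fraction: HCP when any sub-window has
ratio > 0.75 and GC > 0.55, LCP when no sub-window exceeds ratio 0.48, ICP
otherwise. These thresholds follow the convention commonly used for
mammalian promoter classes; the counts are strand-symmetric, so the class
does not depend on which strand is read. Spearman rank correlations between
per-gene region methylation (promoter -500 bp to TSS, or gene body) and
expression are reported overall and per promoter class, with classes below
10 informative genes or constant methylation reported as NA.

## What the generator emulates

`sim_config()` pins the study conditions; the defaults are the conditions
every statistical test in the package is run under:

| parameter | default | meaning |
|---|---|---|
| `chrom_lengths` | 2 x 500 kb | miniature diploid genome |
| `coverage_mean` | 26 | mean WGBS coverage per sample |
| `read_length` | 100 bp | read observations |
| `conversion_failure` | 0.0069 | unconverted-C rate (conversion 99.31%) |
| `spike_in_fraction` | 0.005 | unmethylated lambda-like spike-in |
| `n_controls`, `n_cases` | 4 + 4 | pooled controls, per-case DMRs |
| `snp_rate` | 1/100 bp | heterozygous SNP density |
| `mbias_prob` | 0.05 | extra miscall rate at biased read ends |
| `imprinted_diff_mean` | 0.73 | planted allele difference, imprinted class |
| `nonimprinted_diff_mean` | 0.51 | planted allele difference, other class |
| `dmr_delta` | 0.3 | case-vs-control shift inside a DMR |
| `coupling_fraction` | 0.3 | DEGs given a DMR within 5 kb |

Background CpG methylation is drawn from a bimodal Beta mixture (most mass
near 0 and near 1), islands are hypomethylated, and each gene promoter gets
a shared bimodal methylation state so promoters vary across genes. ASM
regions place both alleles symmetrically around 0.5 with the planted
difference; imprinted regions sit on CpG islands of the first chromosome
(which also carries the annotated imprinted genes) and non-imprinted
regions on moderately CpG-dense segments of the second, so the 1 Mb
classification rule is decidable on a miniature genome. M-bias is an
additive miscall probability on the first 3 positions of mate-1 reads and
the first and last 3 of mate-2 reads; its magnitude is a free parameter,
not a literature value. Half of the het SNPs are forced to be C/T or G/A so
the bisulfite-confounded path is always exercised, and 5% are sire-
heterozygous.

Three generator choices matter for interpretation:

* **SNP density.** 1 SNP per 100 bp condenses, onto a 1 Mb genome, the
  allelic readout an indicine x taurine F1 provides across 2.6 Gb. It makes
  pooled per-allele coverage at testable CpGs ~15-25x, the regime in which
  the 4x rule and the p < 0.01 Fisher threshold have useful power at the
  planted effect sizes (exact power at the 0.01 level: ~0.6 at an allele
  difference of 0.5 and ~0.98 at 0.73, for 18x per allele).
* **Ascertainment inside planted regions.** A SNP-based detector can only
  ever see ASM where informative SNPs exist; a truth region with a SNP
  desert in its middle is invisible to any such method. Planted segments
  are therefore guaranteed het-SNP coverage (max inter-SNP gap 150 bp, SNPs
  kept off CpG dinucleotides), emulating the fact that reported ASM
  catalogues are conditioned on allelic readout being available.
* **Expression coupling.** For genes with HCP/ICP promoters, promoter
  methylation both raises the probability of the gene being near-silent
  and shifts its expected abundance by -8 log2 units per unit methylation;
  LCP genes are uncoupled. This makes the planted negative correlation the
  dominant signal over negative-binomial noise, which is what the
  correlation-recovery tests require the analysis side to find.

What the generator does **not** emulate: paired-end fragment geometry
(mates are independent reads), base qualities, PCR duplicates, alignment
and reference bias, CpH methylation, realistic sequence evolution, and
smoothing-based DMR calling (DMRs are consumed as intervals; truth DMRs are
planted directly). Passing tests therefore demonstrate that the
*statistics* behave as designed under a faithful abstraction of the data,
not that any upstream alignment stack is correct.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere internally; 1-based
  coordinates appear only in VCF I/O. Symmetric CpGs are keyed by the
  plus-strand C.
* Trimming is defined in read orientation (5'->3' of each mate), and the
  coverage filter applies to the strand-merged count.
* The Fisher p sums all hypergeometric outcomes with probability at most
  (1 + 1e-7) times the observed table's, the same tolerance
  `stats::fisher.test` uses; the unit suite checks exact agreement with
  `fisher.test` over every 2x2 table with total at most 30.
* One permutation replicate estimates the FDR by default (`perm_reps`
  averages more), matching the single-randomization arithmetic of the
  ratio estimator.
* Ambiguous reads are dropped; permutation flips only assigned reads, so
  per-CpG allelic coverage is invariant under permutation.
* Degenerate inputs: zero-coverage CpGs have undefined level (NA); a zero
  observed candidate count makes the FDR undefined with a warning; zero
  pooled variance with equal means gives p = 1, with unequal means p = 0
  flagged degenerate; empty interval sets flow through every interval
  operation as empty results.
* The bimodality flag requires both tails occupied (>= 5% of CpGs below
  0.2 and above 0.8) in addition to the tail-mass majority, so a single
  spike at one extreme does not count as bimodal.
* Expression groups resolve the "five groups" ambiguity as floor +
  quartiles (group 1 = near-silent), rather than plain quintiles, so the
  silent class is homogeneous.

## Problem sizes used by the test suite

The statistical acceptance tests run the full stack at the default study
scale: 20 seeds of the 2 x 500 kb, 26x, 4-control design for the null-FDR
calibration and for region recovery; 200 + 50 interval-only datasets
(2 x 5 Mb, 200 genes, 60 DMRs per sample) for the association test's
type-I error and power; 20 seeds for the promoter-coupling recovery; and
1000 shuffles of 50 DMRs for shuffle validity. The interval-only
association geometry is larger and sparser than the read-level genome
because the chi-square comparison needs an expected associated count of
about 6 or more to be in its calibrated regime; the generator skips
sequence synthesis there since only intervals matter.

## Known limitations

* Region boundaries are defined by candidate CpGs, so detected regions are
  slightly narrower than planted truth when edge CpGs fall just short of
  the candidate threshold.
* The permutation FDR uses a single global candidate-count ratio; it is
  not a per-CpG local FDR.
* The chi-square association test assumes approximately independent DEG
  associations; heavily clustered genes sharing one DMR would inflate its
  variance.
* `scan_dmrs_naive()` exists to close the loop in self-contained runs and
  is intentionally excluded from all validation claims.

## A complete run

```{r, eval = FALSE}
cfg <- sim_config(seed = 1)
ds <- simulate_dataset(cfg)
controls <- ds$read_sets[ds$groups == "control"]

scan <- asm_scan(controls, ds$ref, ds$truth$het_snps,
                 imprinted_genes = ds$ref$imprinted_genes, seed = 7)
summary(scan)

tab <- coverage_filter(
  pileup_cpgs(lapply(controls, trim_reads), ds$ref,
              snps = ds$truth$het_snps), 5)
methylation_summary(tab, ds$ref$cpg_islands)

degs <- ds$truth$deg_truth[ds$truth$deg_truth$is_deg, ]
dmrs <- ds$truth$dmrs[ds$truth$dmrs$sample_id == "case_1", ]
permutation_expectation(degs, dmrs, ds$ref$chrom_lengths, ds$ref$gaps,
                        extension = 5000, n_shuffles = 1000, seed = 7)
```
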