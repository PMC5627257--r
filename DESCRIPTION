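Package: asmscout
Title: Allele-Specific DNA Methylation Detection and Methylome-Transcriptome
    Association in F1 Hybrids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects allele-specific DNA methylation (ASM) from whole-genome
    bisulfite sequencing read observations of F1 hybrid individuals, using
    parental-origin read assignment at heterozygous SNPs, per-CpG Fisher exact
    tests with a label-permutation false discovery rate, and clustering of
    candidate CpGs into characterized ASM regions. Also quantifies spatial
    association between differentially methylated regions and differentially
    expressed genes through a chromosome- and length-preserving interval
    shuffling null with a chi-square goodness-of-fit test, and profiles the
    methylome against the transcriptome (metagene profiles by expression
    group, CpG-density promoter classes, promoter and gene-body
    methylation-expression correlations). A self-contained simulator
    generates miniature diploid genomes, bisulfite read observations with
    conversion failure and read-end bias, an unmethylated spike-in control,
    and expression counts with planted truth, so the whole pipeline is
    testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    vcfR
Config/testthat/edition: 3
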