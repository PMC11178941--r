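Package: epivar
Title: Linking Environment-Induced and Strain-Selective Histone Acetylation
    Changes to Sequence Variants and GWAS Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for relating differential and strain-selective H3K27ac
    region atlases to genome sequence variants and human disease associations.
    Builds variant-incorporated consensus genomes with UCSC chain files and
    lifts intervals between the two coordinate systems; constructs
    non-overlapping long-range cis-regulatory element domains (LCREDs) by the
    GREAT "single nearest gene" rule and assigns regions to genes by interval
    midpoint; merges and classifies region sets across conditions and strains;
    computes SNV/indel densities per interval, per domain, and per chromatin
    state; scans position weight matrices and scores allelic affinity change;
    links H3K27ac classes to expression fold changes; and tests GWAS
    disease/trait enrichment with a GREAT-style binomial test over an LCRED
    universe with Benjamini-Hochberg FDR. A synthetic-data module generates
    genomes, annotations, labeled region sets, variants, GWAS catalogs, and
    negative-binomial counts with the statistical structure the analysis
    assumes, so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    DESeq2,
    rtracklayer,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
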