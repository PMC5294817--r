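Package: cistrovar
Title: Integrating Transcription Factor Cistromes with GWAS Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Workflow for integrating a transcription factor's consensus
    ChIP-seq cistrome with GWAS lead SNPs and their linkage-disequilibrium
    proxies. Provides consensus peak merging across datasets, SNP-to-peak
    assignment, r-squared proxy expansion from phased haplotype panels,
    per-phenotype hypergeometric enrichment with Bonferroni correction,
    direct-repeat (DR3) motif scanning with allele-aware delta-LOD scoring,
    regulatory-score classification, fractional-overlap intersection of two
    cistromes, and seeded synthetic-data generators that emulate every input
    so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    Biostrings,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
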