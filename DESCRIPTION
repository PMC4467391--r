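Package: cnevolve
Title: Copy-Number and Mutation Clonality Across Tumor Progression
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multi-sample analysis of somatic genome evolution from paired
    tumor/normal sequencing coverage. Implements pseudo-CGH copy-number
    profiling from read-count windows (log2 ratios with median centering and
    BAF-guided aneuploidy baseline correction), B-allele frequencies at
    germline heterozygous SNP sites, penalized changepoint segmentation with
    a minimum-probe rule, classification of copy-number events into graded
    loss/gain categories with clonal versus subclonal calls and cell-fraction
    estimates, somatic point-mutation filtering and cross-sample clonality
    tracking (including detection of subclone purification), and
    megabase-concordance-based classification of linear versus parallel
    metastatic progression. A seeded clone-tree simulator generates paired
    count data, SNP allele counts and variant tables so the whole pipeline is
    testable without access to patient sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
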