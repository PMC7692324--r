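Package: methylminr
Title: Quartile-Based Mining of Cancer- and Tissue-Specific CpG Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines Illumina 450K-style beta-value matrices from paired
    tumor/normal cohorts of multiple cancer types for CpG probes with
    distinct methylation profiles. The core classifier compares the first
    and third quartiles of each (cancer, tissue) group against
    hyper/hypomethylation thresholds to call cancer-specific and
    tissue-specific hyper/hypomethylated probes. Also provides a
    pathway-restricted tumor-versus-normal differential methylation test
    (Mann-Whitney with BH adjustment and volcano classification),
    semi-unsupervised hierarchical clustering of filtered probes,
    methylation-expression Pearson correlation, a synthetic multi-cancer
    cohort generator with planted probe classes, and a subcommand
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    ape,
    pheatmap,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
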