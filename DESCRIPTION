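Package: bsascan
Title: Bulked-Segregant-Analysis Sequencing Scans for QTL Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects quantitative trait loci from pooled whole-genome
    sequencing of phenotypic extremes (bulked segregant analysis by
    sequencing). Provides allele-count ingestion from TSV, VCF allelic-depth
    and PoPoolation2 sync records, coverage and control-pool SNP filters,
    a sliding-window two-pool Z statistic with empirical outlier
    thresholding, QTL region calling with boundary extension and merging,
    interval overlap reports against linkage-mapping QTL, genetic-map
    expansion factors for intermated and inbred designs, and a
    forward-in-time simulator of intermated biparental populations with
    truncation selection and pooled sequencing for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    ggplot2,
    jsonlite
Config/testthat/edition: 3
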