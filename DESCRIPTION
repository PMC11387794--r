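Package: cocusig
Title: Tumor-Stroma Crosstalk Gene Signatures from Co-Culture Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives cancer cell/fibroblast crosstalk gene signatures from
    paired mono-culture and co-culture expression profiles, using either
    pathway-frequency selection over gene set enrichment results or
    fold-change intersection across datasets. Includes a weighted
    Kolmogorov-Smirnov gene set enrichment implementation with gene-set
    permutation, a two-component mixture model for correcting
    cross-contamination in sorted co-culture samples, per-sample signature
    scoring, quartile-stratified survival analysis (Kaplan-Meier, log-rank,
    Cox regression), and a multi-region tumor concordance test against an
    analytic chance expectation. Ships synthetic-data generators that emulate
    the statistical structure of each analysis so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    knitr,
    rmarkdown
Config/testthat/edition: 3
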