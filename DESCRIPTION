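Package: sccmosaic
Title: Defining and Comparing Cancer Stem Cell Populations in Glioblastoma Single-Cell Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to call slow-cycling, fast-cycling, and marker-high cancer
    stem cell populations from single-cell TPM expression matrices, quantify
    their overlap structure, test differential expression between private-cell
    cohorts with an empirical-Bayes moderated t-statistic, project population
    character onto bulk cohorts by signature-matrix deconvolution, stratify
    patients for survival comparison, and rank drug-target gene sets by
    enrichment. Includes a synthetic-data generator with planted ground truth
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    pracma,
    survival,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
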