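Package: bindscape
Title: Differential Transcription Factor Binding and Chromatin
    Accessibility Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Classifies multi-condition differential transcription factor
    binding from ChIP-seq tag data with a negative-binomial exact test,
    quantifies prior chromatin accessibility at binding-site sets from
    ATAC-seq (accessible domains, per-site densities, composite
    profiles), scans position weight matrices against Markov sequence
    backgrounds with empirical false-discovery-rate score thresholds, and
    tests association between binding-site categories and
    differential-expression gene sets by logistic regression.  Ships a
    synthetic-data generator that plants binding landscapes with known
    motif composition, accessibility state and per-factor occupancy, so
    the whole pipeline can be exercised against ground truth.
License: MIT
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
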