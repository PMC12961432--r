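Package: nrlfit
Title: Nucleosome Repeat Length Estimation from Sequenced Fragment Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the nucleosome repeat length (NRL) from paired-end
    fragment intervals produced by MNase-seq, ATAC-seq or cell-free DNA
    sequencing. Implements phasogram (distance autocorrelation) analysis of
    nucleosome dyads and fragment starts, regression of periodic peak summits
    of the fragment-size distribution, anchored aggregate-profile peak
    spacing, and chromatin-state-stratified NRL estimation. Includes a
    synthetic nucleosome-array simulator with known ground-truth NRL so every
    estimator can be validated by parameter recovery, and a command-line
    interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
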