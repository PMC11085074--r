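Package: grnhist
Title: Gene Regulatory Network Inference from Joint-Expression Histograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers transcription factor (TF) to target-gene regulatory
    interactions from paired bulk and single-cell RNA-Seq expression.
    Each candidate gene pair is converted into a stacked 2D histogram of
    joint expression across samples and cells, scored by a small
    convolutional neural network trained on gold-standard TF-target
    pairs, and thresholded into a genome-wide regulatory network.
    Includes a paired bulk/single-cell expression simulator with planted
    regulatory structure, permutation-based network overlap enrichment,
    per-TF hypergeometric target overlap with Benjamini-Hochberg
    adjustment, and GO-based TF function inference with recovery-rate
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
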