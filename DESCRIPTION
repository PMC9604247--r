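Package: methylseg
Title: Distance-Aware Hidden Markov Segmentation of CpG Methylomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segmentation of bisulfite-sequencing methylomes into methylation
    regimes with a hidden Markov model tailored to sparse single-cell data:
    binomial emissions over per-CpG methylated/unmethylated counts, transition
    probabilities that decay towards independence with genomic distance between
    neighbouring CpGs, read-depth-weighted Baum-Welch training, and
    bidirectional Viterbi decoding that marks direction-discordant sites as
    unknown. Includes readers for Bismark coverage and cytosine-report files
    with single-cell coverage-artifact filtering, hypomethylated-locus and
    cell-type-specific locus calling, permutation tests for feature enrichment,
    descriptive methylome statistics (global, per-feature, binned, rank
    correlation between samples), bisulfite-converted reference construction
    for tandem-repeat methylation, and a synthetic methylome generator matched
    to the model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
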