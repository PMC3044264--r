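Package: epifilter
Title: Ensemble ReliefF and TuRF Filtering of SNP-SNP Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Filtering of case-control SNP genotype data prior to combinatorial
    gene-gene interaction analysis. Implements the ReliefF family of
    multivariate filters (ReliefF, tuned ReliefF/TuRF, SURF, SURFTuRF) for
    categorical genotype data, together with their sample-order-permutation
    ensembles (ReliefF-E, TuRF-E) that aggregate SNP rankings across runs to
    remove the k-nearest-neighbour tie-breaking instability of the base
    algorithms. Also provides univariate chi-squared and odds-ratio
    comparator filters, a two-locus purely epistatic penetrance-model
    simulator with controlled heritability and no marginal effects, and an
    evaluation toolkit (rank-stability correlation, tie-causing-sample
    detection and removal, percentile success rates and average cumulative
    success rate, ensemble-size sweeps). Reads and writes the MDR flat-file
    genotype format.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
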