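Package: peptideSA
Title: Surrogate-Guided Simulated Annealing Design of Plastic-Binding Peptides
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sequence-only design of material-binding peptides. Recurrent
    neural-network regressors (LSTM by default; BiLSTM, GRU, vanilla RNN and a
    small Transformer for comparison) are trained on peptide sequence-score
    tables to act as fast surrogates for a biophysical affinity score, and a
    simulated-annealing designer with Metropolis acceptance optimizes
    single-material affinity, multi-material promiscuity (mean score) or
    pairwise selectivity (score difference) over 12-residue peptide space.
    Includes a synthetic additive-plus-epistatic score-landscape generator for
    fully offline training and benchmarking, plus post-campaign analyses:
    novelty against a reference set, greedy Hamming-distance diversity
    selection, amino-acid composition profiles and composition correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
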