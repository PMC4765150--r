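Package: smrf
Title: Structure-Based Markov Random Field Coevolution Analysis
Version: 0.1.0
Authors@R: person("SMRF", "Maintainers", email = "smrf@example.org",
    role = c("aut", "cre"))
Description: Fits a sparse Potts/Markov random field, whose edge set is the
    intramolecular contact map of a protein structure (C-beta distances
    below 8 Angstrom), to a multiple sequence alignment by L2-regularized
    pseudo-likelihood with L-BFGS. Derives pairwise coevolution scores from
    edge-weight norms with average-product correction, positional
    coevolution scores (node-weight KL divergence, proximity average,
    coevolving-contact fraction) and KLD/JSD conservation scores, plus
    ROC/AUC evaluation utilities and a synthetic-data generator (planted
    sparse Potts models, Gibbs-sampled alignments, toy structures) for
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr (>= 2.0.0),
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
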