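Package: hpdca
Title: Hopfield-Potts Direct Coupling Analysis for Residue Coevolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers attractive and repulsive sequence patterns from the
    spectrum of the Pearson residue-correlation matrix of a protein
    multiple-sequence alignment, builds low-rank direct couplings from a
    maximum-likelihood-selected subset of patterns, and predicts
    residue-residue contacts via average-product-corrected Frobenius
    scores.  Includes a Gibbs sampler for the generative model and
    synthetic alignment generators so the whole pipeline can be exercised
    without external data, plus optional evaluation of predictions
    against a protein structure.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Biostrings,
    bio3d,
    Rcpp,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
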