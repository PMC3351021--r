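Package: ecforest
Title: Enzyme Function Class and Sub-Class Prediction from Sequence Features
Version: 0.1.0
Authors@R:
    person("ecforest", "maintainers", email = "ecforest@example.org",
           role = c("aut", "cre"))
Description: Predicts whether a protein sequence is an enzyme and, if so, its
    Enzyme Commission (EC) main class (1-6) and sub-class (X.Y), from 73
    physicochemical features computed directly from the amino-acid sequence
    (composition, dayhoffstat, molecular weight, theoretical pI, GRAVY,
    aliphatic and instability indices, atom counts, and property-class
    compositions). Provides a three-tier top-down random-forest cascade
    (enzyme/non-enzyme, main class, sub-class) and a direct single-step
    sub-class model, out-of-bag grid tuning of forest parameters,
    carry-over-adjusted precision and recall that propagate main-class errors
    into sub-class reporting, permutation-based feature importance, and a
    synthetic sequence generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
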