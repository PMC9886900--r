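Package: helr
Title: Privacy-Preserving Cancer-Type Prediction from Somatic Mutations
    Under Homomorphic Encryption
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Gene-level encoding of somatic single-nucleotide and copy-number
    variants, chi-square feature selection, and an L1-penalized multinomial
    logistic regression whose argmax inference can be evaluated on encrypted
    patient data.  Includes a self-contained BFV homomorphic-encryption
    engine (RNS number-theoretic transforms, slot batching, Galois
    rotations) implementing a packed matrix-multiplication algorithm with
    fixed-point CRT plaintext encoding, a bit-exact plaintext simulator of
    the encrypted circuit, and a synthetic-cohort generator for end-to-end
    testing without access to protected genomic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp (>= 1.0.0),
    glmnet,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
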