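Package: ktheta
Title: Species Delimitation from DNA Sequences with the K/theta Ratio
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Delimits evolutionary species from single-locus DNA sequence
    samples using the K/theta ratio: within-clade nucleotide diversity
    (theta = 2*Ne*mu) is estimated from mean pairwise differences, the
    divergence K between well-supported sister clades on a bootstrapped
    neighbor-joining tree is compared against it, and sister clades with
    K/theta >= 4 are classified as independently evolving species.
    Includes Jukes-Cantor, Kimura two-parameter and Kimura three-substitution-
    type distance corrections, a two-population coalescent simulator for
    reciprocal-monophyly probabilities and for generating synthetic test
    data, and a reproducible report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
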