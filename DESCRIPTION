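Package: supersigr
Title: Supervised Mutational Signatures of Variable Context Length
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised discovery of tissue-specific mutational signatures
    (SuperSigs) from somatic mutation profiles with clinical annotation.
    Builds per-sample 96-context substitution profiles from MAF-like tables,
    engineers predictive features of variable context length (1-3 bp) on the
    151-node mutational family tree via ancestor-conditional one-sided
    binomial tests, selects features by cross-validated AUC, and represents a
    signature by mean count/rate differences and logistic regression
    coefficients. Also provides the comparison baselines (random single-peak
    signatures, NMF via multiplicative updates, partially supervised NMF),
    non-negative least squares attribution, aging-proportion estimation,
    mutational-landscape distances, and a synthetic cohort generator with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
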