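Package: subsig
Title: Signature-Regularized Cancer Subtype Discovery and Copy-Number Driver
    Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers cancer expression subtypes by iterating between
    clustering of tumor samples and detection of subtype-specific gene
    signatures, so that every reported subtype is backed by a sizable set of
    genes differentially expressed in that subtype alone.  Given externally
    pre-selected copy-number-aberration candidate genes, ranks them per
    subtype by their overall correlation with the subtype signature, using an
    SVD projection of the signature-by-candidate covariance matrix and a
    permutation null built from random gene sets.  Includes cross-dataset
    validation by two-moment gene-wise normalization and k-nearest-neighbor
    label transfer, and synthetic-data generators that plant known subtype
    structure and known driver-signature dependencies for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
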