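Package: codonflux
Title: Codon Usage, tRNA Anticodon Pools, and Translational Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether the codon usage of mammalian gene sets
    is tuned to the cellular tRNA anticodon pool. Implements canonical
    coding-sequence selection and codon counting, a size-matched resampling
    null for gene-set codon-usage divergence from the exonic background,
    expression-weighted codon usage and three translational-efficiency
    statistics (strict codon-anticodon pairing, wobble-aware pairing, and an
    expression-based tRNA adaptation index), match/mismatch cross-condition
    contrasts with one-tailed rank tests, and a PCA/GC-content decomposition
    of per-gene-set codon usage. A seeded synthetic-data generator emulates
    coding sequences with a GC gradient, overdispersed mRNA and tRNA counts,
    and anticodon pools with a tunable degree of adaptation, so the whole
    pipeline runs and can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
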