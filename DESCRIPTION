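Package: famseg
Title: Family-Based Rare-Variant Prioritization with Expression Conjoint Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for prioritizing rare candidate variants in
    families segregating a common complex disease, modelled on family designs
    used for house-dust-mite allergic rhinitis. Implements variant quality and
    cluster filtering, functional-consequence annotation on minimal transcript
    models (HGVS c./p. rendering, canonical splice-site calls), affected
    parent-child heterozygous co-segregation, cross-family shared-gene
    detection, a two-group differential-expression stage, conjoint intersection
    of segregation candidates with differentially expressed genes,
    hypergeometric/EASE gene-set enrichment, compound-heterozygote flagging,
    serology-based cohort eligibility utilities, and a deterministic synthetic
    data generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    vcfR,
    fgsea,
    Biostrings,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
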