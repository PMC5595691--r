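Package: agerank
Title: Ranking Drug-Like Compounds for Their Likelihood of Modulating
    Aging in Invertebrate Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An empirical scoring and ranking procedure for drug-like
    compounds with known mammalian protein targets, prioritising them for
    lifespan experiments in Caenorhabditis elegans and Drosophila
    melanogaster. Five multiplicative factors (aging implication from Gene
    Ontology evidence codes, Grantham-similarity-based domain and
    binding-site conservation mapped through family alignments, a logistic
    transform of predicted log binding affinity, and species-specific
    bioavailability) are combined with four additive terms (Lipinski
    rule-of-five loss, binding-promiscuity loss, purchasability and drug
    approval bonuses) into a bounded composite score. Includes readers for
    aligned FASTA families and flat annotation tables, a deterministic
    synthetic-data generator with an independent scoring oracle,
    species-specific rankings with score-distribution cutoffs, and
    per-compound report cards in JSON, HTML and TSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
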