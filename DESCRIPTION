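Package: phenoquery
Title: Ontology-Based Querying of Phenotype-Genotype Relationships in
    Patient Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents patient cohorts with genetic variants and
    three-valued (present / absent / unknown) phenotype assertions under
    open-world semantics, loads an is-a phenotype ontology, forward-chains
    Horn-like abstraction rules that derive catalog-level phenotype
    descriptions (such as childhood-onset chronic diarrhea) from raw
    clinical fields, and evaluates bidirectional phenotype-genotype query
    patterns with hierarchy expansion and set or aggregate answers. Ships
    a constraint-verified synthetic cohort emulating a cerebrotendinous
    xanthomatosis (CTX) study of 25 patients with CYP27A1 variants, and a
    seeded random-cohort generator for property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
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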