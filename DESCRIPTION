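Package: phenodiff
Title: Term-Wise Phenotype Frequency Comparison of Patient Groups over
    an HPO-Style Ontology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Compares the phenotypic spectra of two gene-defined patient
    groups annotated with Human Phenotype Ontology (HPO) terms.  Observed
    annotations are propagated to all ancestor terms (the true-path rule),
    per-term patient counts are tabulated per group, and each term is
    tested with a Pearson chi-squared test on the 2x2 contingency table,
    omitting terms with any expected cell count below 5 and applying a
    Bonferroni correction over the tests actually performed.  Includes an
    OBO flat-file reader, readers for curated case-report tables, a
    seeded synthetic-cohort simulator for power and type-I studies, a
    count-table realiser that constructs cohorts reproducing published
    per-term counts, and packaged fixtures for the inherited
    GPI-deficiency cohort (two pathway-stage gene partitions and the
    published per-term count tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma
Config/testthat/edition: 3
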