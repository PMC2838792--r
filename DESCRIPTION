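Package: cladelink
Title: Behavioral Symptom Networks and Clade-Conditioned Genetic Linkage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dissects phenotypic heterogeneity in family studies of
    neuropsychiatric disorders by building a character-based (parsimony)
    network over individuals from their behavioral symptoms, nesting the
    consensus network into increasingly inclusive clades, testing each
    clade as a candidate endophenotype with two-point parametric linkage
    under an admixture heterogeneity model (HLOD), profiling clade
    symptoms with a four-group binomial likelihood-ratio test, and
    assessing significance with gene-dropping and permutation empirical
    p-values. Includes a synthetic-data module emulating the GAW14
    "Kofendred Personality Disorder" simulation so that every stage is
    testable with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
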