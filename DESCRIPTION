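Package: srnafrag
Title: Small RNA Fragment Profiling, tRNA-Derived Fragment Classification
    and Mitochondrial Small RNA Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for sperm-like small RNA sequencing
    libraries: adapter trimming and read collapsing with a cross-sample
    evidence rule, exact-match mapping against hierarchical biotype
    references and nuclear/mitochondrial genomes, classification of
    tRNA-derived fragments (tsRNA) into five cut-site subtypes from
    tRNAscan-SE secondary structures, counts-per-million normalisation with
    two-stage abundance filtering, sequence- and feature-level log2 fold
    changes, negative-binomial GLM differential testing, repeated-measures
    correlation with sample phenotypes, and a synthetic-data generator with
    planted group effects for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    knitr,
    MASS,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
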