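Package: selproc
Title: Classification and Simulation of Selection Processes in
    Epidemiological Research
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for representing selection processes on time-indexed
    causal diagrams and studying their consequences for epidemiological
    effect estimation. Provides a time-indexed causal DAG data model with
    role annotations, an automatic classifier that places every selection
    process in a three-dimensional framework (selection level, mechanism,
    timing), a binary structural-causal-model engine with exact joint
    enumeration, conditioning by nature and seeded cohort sampling, and
    risk-based effect estimators (crude, stratified, Mantel-Haenszel,
    standardized and inverse-probability-weighted risk ratios). A registry
    of ready-made scenarios covers the classical selection phenomena:
    healthy worker hire and survivor effects, index event bias, competing
    events, depletion of susceptibles, reversed causality and Berkson's
    fallacy.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
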