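Package: mskit
Title: Sex-Limited Chromosome Read Sorting with Population-Specific K-mers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies sex-limited-chromosome-specific k-mers (e.g. Y-specific
    markers) from male and female population short reads, sorts long reads and
    contigs by marker density, and provides closed-form Poisson/binomial error
    models for the marker-identification and read-sorting processes. Includes a
    synthetic genome, population and long-read simulator with ground-truth
    labels so every stage of the pipeline is verifiable at desk scale, plus
    evaluation utilities (precision/recall/F1 against truth, population-size
    and marker-precision sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
SystemRequirements: zlib
Config/testthat/edition: 3
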