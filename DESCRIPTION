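Package: microload
Title: Absolute Bacterial Abundance from Equivolumetric 16S Amplicon Sequencing
Version: 1.0.0
Authors@R:
    person("microload", "authors", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Estimates absolute bacterial abundance, in colony-forming units
    (CFU), from 16S rRNA amplicon read counts generated under an equivolumetric
    library-preparation protocol. Provides read-level quality and primer
    filters, count-table decontamination and cross-run normalization, Bayesian
    cumulative probability (proportional-odds) models for total microbial load
    and, hierarchically, for taxon-specific abundances with partial pooling
    across taxa, full posterior prediction machinery (class probabilities,
    expectations, tail probabilities, predictive class intervals), a
    cross-validation and metric suite, and a synthetic mock-dilution data
    generator for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    survival,
    optparse,
    Biostrings,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
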