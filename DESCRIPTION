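Package: sensorscreen
Title: Barcoded Biosensor Library Screening with Bacterial Memory Circuits
Version: 0.1.0
Authors@R:
    person("Screening", "Pipeline Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for pooled screens of bacterial biosensor
    libraries built on a lambda-phage memory circuit. Mines 'grouped'
    two-component systems (a histidine kinase / response regulator pair next
    to a divergently transcribed gene) from annotated genomes and classifies
    Type IIS (SapI/BsaI) Golden Gate cloning compatibility; derives reference
    DNA barcodes from short-read amplicon data by length filtering and greedy
    95 percent identity clustering; links barcodes to sensors with long reads
    spanning the sensor-barcode junction under a dual-criterion assignment
    rule; quantifies memory-circuit activation as fractional odds ratios
    (FOR) normalised against positive and negative control strains, with
    sample-level quality-control gates; and ranks condition-responsive
    sensors. A fully seeded synthetic-data generator emulates library
    composition, bacteriostatic spectinomycin selection, multinomial read
    sampling, sequencing error and colonisation bottlenecks, providing ground
    truth for every stage.
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
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
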