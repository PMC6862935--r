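Package: phenoQTL
Title: Time-Series Phenology, Heritability and QTL Mapping for Biparental
    Field Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for extracting heading date and rate of heading from
    time-series percent-heading scores of wheat field plots via per-plot
    logistic growth curves, estimating variance components and broad-sense
    heritability by REML under iid or separable AR1xAR1 spatial residuals,
    and mapping the genetic architecture of the extracted traits in
    recombinant inbred line (RIL) populations: marker filtering,
    single-marker association scans with Bonferroni control, two-way
    epistasis scans, two-gene segregation tests, and G-BLUP genomic
    prediction with cross-validation. Includes the label machinery used
    around image classifiers scoring the same plots (label imputation
    between scoring dates, soft-label target distributions with
    partial-credit error, patch-grid geometry, and consensus voting), and a
    synthetic-data generator that simulates RIL genotypes with Haldane
    recombination, epistatic trait architectures, replicated field trials
    with spatially correlated noise, and discretized visual scores with a
    calibrated mislabel model, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    withr,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
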