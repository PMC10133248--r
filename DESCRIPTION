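Package: ddrprofiler
Title: Functional DNA Damage Response Profiling of Tumour Explants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the five canonical DNA damage response (DDR) pathways
    (homologous recombination, non-homologous end joining, base-excision,
    nucleotide-excision and mismatch repair) from per-cell functional assay
    readouts: Rad51/gamma-H2AX nuclear foci, host-cell reactivation GFP
    reporter events, four-condition alkaline comet tables and
    impact-annotated variant panels. Fits growth-rate-adjusted (GR50)
    carboplatin dose-response curves, classifies reactive-oxygen-species
    recovery and mitochondrial membrane states, assembles explant and
    patient signatures with class-balance survivorship and heterogeneity
    metrics, classifies survival-horizon outcomes (regularised linear
    discriminant, perceptron network, RBF support vector machine) with
    cross-validation, and performs PCA and multiple correspondence analysis.
    A synthetic-cohort generator with planted ground truth makes every stage
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    nnet,
    e1071,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    pROC,
    vcfR,
    optparse
Config/testthat/edition: 3
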