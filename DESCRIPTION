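Package: photothermal
Title: Photoperiod Response Modelling and Energy Budgeting for Speed Breeding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing flowering-time experiments in long-day
    cereals grown under extended photoperiods. Implements the bi-linear
    (linear-plateau) photoperiod response model with three interpretable
    parameters (intrinsic earliness, photoperiod sensitivity, threshold
    photoperiod), maximum-likelihood fitting with profile search over the
    breakpoint, model-variant comparison and responder classification, a
    synthetic-data generator mirroring a multi-genotype growth-tent design,
    pairwise photoperiod treatment contrasts, qPCR relative-expression
    analysis (delta-Ct), and a lighting energy/cost model for
    genotype-tailored speed-breeding photoperiods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
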