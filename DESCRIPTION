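Package: synergyMoA
Title: Anchored Drug-Combination Synergy Screening and Mechanism-of-Action
    Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative pipeline for anchored drug-combination viability
    screens and downstream mechanism-of-action profiling. Provides plate
    quality control (Z-prime), four-parameter log-logistic dose-response
    fitting with normalized area-under-curve statistics, Bliss-independence
    synergy scoring over fixed anchor doses, competition-pulldown
    (Kinobeads-style) target calling with depletion-corrected apparent
    dissociation constants, and dose-resolved phosphoproteomic regulation,
    reversal and consensus calling including pSQ/pTQ substrate-motif
    annotation. A synthetic-data module generates all input kinds with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'doseResponse.R'
    'plateQC.R'
    'synergy.R'
    'kinobeads.R'
    'phospho.R'
    'simulate.R'
    'pipeline.R'
    'synergyMoA-package.R'
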