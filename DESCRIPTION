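Package: viscnet
Title: Visceral Network Glucose Imaging and Microbiome Biomarker Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies pre-systemic and post-systemic glucose handling of the
    gut, visceral fat and liver from intraperitoneal FDG-PET time-activity
    curves, scores liver histology for steatohepatitis with a Kleiner-adapted
    composite, discovers microbial biomarkers with a two-stage LDA effect-size
    procedure on total-sum-scaled abundance tables, and screens associations
    between imaging metrics and taxa under false-discovery-rate control. A
    seeded synthetic-cohort generator with a linear compartmental tracer model
    makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'io-formats.R'
    'kinetics.R'
    'cohort.R'
    'taxa.R'
    'pet-quant.R'
    'histology.R'
    'lefse.R'
    'associations.R'
    'pipeline.R'
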