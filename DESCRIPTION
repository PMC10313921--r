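Package: sliceDSS
Title: Drug Sensitivity Scoring for Ex Vivo Brain-Slice Drug Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes multi-parametric drug sensitivity scores (DSS) for ex
    vivo organotypic brain-slice culture (OBSC) drug screens. Normalizes
    tumor bioluminescence to day-one fluorescence and untreated controls,
    anchors propidium-iodide toxicity between healthy and dead-control
    references, derives interpolation-based dose-response metrics (ECx/ICx
    with not-reached semantics, slope through the EC50, normalized AUC,
    curve-shape diagnostics), combines tumor kill and normal-tissue toxicity
    into eleven weighted therapeutic windows on the [-1, +1] scale, and
    aggregates them into a single score on the [-100, +100] scale per
    drug-tumor pair. Includes batch-level slice-viability quality control, a
    seeded synthetic assay generator with an analytic dense-grid oracle, and
    CSV/JSON reporting suitable for screening pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'assay-normalize.R'
    'curve-metrics.R'
    'windows.R'
    'dss.R'
    'qc.R'
    'synthetic.R'
    'orchestrate.R'
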