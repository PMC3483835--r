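Package: proteoturn
Title: Simulation and Critical Appraisal of Protein Degradation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic kinetic model of cellular protein turnover coupling
    mRNA synthesis and decay, translation, protein degradation and growth
    dilution. Simulates the standard experimental designs used to measure
    protein half-lives (cycloheximide chase, Tet-off transcriptional shutoff,
    siRNA knockdown, degradation-inhibitor treatment, radioactive pulse-chase,
    SILAC label switch), adds replicate measurement noise, fits half-lives by
    log-linear, nonlinear one-exponential and model-free t50 estimators, and
    quantifies how mRNA decay confounds apparent protein half-lives in shutoff
    designs. Includes a deterministic evidence-grading engine encoding a
    checklist for the critical appraisal of protein degradation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    minpack.lm,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'kinetics.R'
    'scenario.R'
    'measurement.R'
    'estimation.R'
    'appraisal.R'
    'io.R'
    'zzz.R'
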