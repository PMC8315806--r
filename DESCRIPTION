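Package: bbsmap
Title: Brain-Behavior Space Mapping for Psychosis Spectrum Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping low-dimensional clinical symptom geometry onto
    parcellated resting-state global brain connectivity (GBC). Implements
    frame scrubbing and parcel-level GBC computation, unit-variance symptom
    principal component analysis with permutation significance and held-out
    score projection, a generic resampling harness (leave-site-out, k-fold,
    split-half, leave-one-out), mass-univariate symptom-neural mapping with
    max-statistic family-wise error control and shared neural-variance
    partialling, canonical correlation analysis with mode significance,
    cross-validation and a generative power analysis for required sample
    size, dot-product GBC (dpGBC) step-down parcel selection, reference-map
    benchmarking, and a synthetic cohort generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
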