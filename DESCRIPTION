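Package: emobio
Title: EEG Biomarkers of Facial-Expression Mental Imagery
Version: 0.1.0
Authors@R: person("emobio", "developers", role = c("aut", "cre"),
    email = "emobio@example.org")
Description: A tested pipeline for extracting candidate EEG biomarkers of
    mental imagery of facial expressions and classifying subjects into two
    groups. Provides a synthetic cohort generator (trial-structured paradigm,
    1/f background plus band-limited oscillations with injectable group
    effects), offline preprocessing (zero-phase band-pass and notch
    filtering, average reference, epoching, bad-epoch rejection, baseline
    correction, ERP averaging), band-limited linear and non-linear feature
    extraction (envelope, Teager-Kaiser energy, instantaneous power, spatial
    filling index, largest Lyapunov exponent, correlation dimension,
    approximate and sample entropy on time-delay embeddings), a from-scratch
    WiSARD weightless neural network with bleaching, a linear support vector
    machine, and a repeated stratified holdout evaluation harness with
    per-fold t-ranked feature selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    data.table,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
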