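Package: anesdepth
Title: Depth-of-Anesthesia Estimation from Two-Channel ECoG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for estimating instantaneous anesthetic depth
    from two-channel epidural electrocorticogram (ECoG) recordings under a
    piecewise-constant isoflurane protocol with concurrent whisker
    stimulation. Provides a synthetic ECoG generator with known hidden depth
    (burst suppression, depth-dependent interhemispheric coherence, 1/f
    background, line noise, attenuating evoked responses), zero-phase
    preprocessing, windowed spectral and complexity features (Welch power
    spectra, spectral edge frequency, aperiodic slope, band powers,
    magnitude-squared coherence, sample entropy, Lempel-Ziv complexity,
    burst-suppression metrics), evoked-response-attenuation targets,
    Mann-Whitney/Benjamini-Hochberg modulation statistics, and a
    lagged-feature gradient-boosted tree regressor evaluated under
    leave-one-animal-out cross-validation with Gini-gain feature importances
    and an elapsed-time control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    xgboost,
    yaml
LinkingTo: Rcpp
Suggests:
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
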