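Package: sleepenv
Title: Sleep EEG Envelope Spectrum Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterization of the sleep EEG envelope: band-limited
    Hilbert-envelope extraction, artifact-adaptive "colliding window"
    estimation of the envelope power spectral density, envelope-to-neuronal
    firing (multi-unit activity) coupling statistics with surrogate-based
    inference and false-discovery-rate control, within-subject reliability
    of envelope spectra, and multivariate phenotype prediction from
    envelope spectral features with elastic-net regression. Includes a
    synthetic-data generator (amplitude-modulated test signals in pink
    noise, envelope-coupled firing proxies, phenotype cohorts) so that
    every stage of the pipeline can be exercised without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    glmnet,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
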