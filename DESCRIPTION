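Package: opmbeta
Title: Beta-Band Burst and Connectivity Analysis for OPM-MEG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Source-space analysis of wearable optically pumped magnetometer
    magnetoencephalography (OPM-MEG) recordings from somatosensory paradigms,
    together with a synthetic cohort generator for validating every stage by
    parameter recovery. Implements preprocessing (bad-channel and
    high-variance-trial rejection, notch and band-pass filtering, homogeneous
    field correction), an analytic conducting-sphere forward model with LCMV
    beamforming and pseudo-T beta-modulation imaging, Hilbert-envelope
    time-frequency and beta modulation metrics, orthogonalized
    amplitude-envelope-correlation connectomes, pan-spectral burst detection
    with a three-state time-delay-embedded hidden Markov model, and
    cohort-level neurodevelopmental trend estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
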