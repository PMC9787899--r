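Package: stepforce
Title: Predicting Vertical Ground Reaction Forces in Running from Footstep Sounds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct vertical ground reaction force (vGRF) curves
    during running from the linear envelopes of footstep sounds. Raw force-plate
    and microphone recordings are filtered, segmented into stance phases and
    body-weight normalized; each stance-aligned curve is represented by a
    truncated Fourier series, and vGRF coefficients are predicted from sound
    coefficients plus body mass, running speed and stance time by a
    conditional-Gaussian maximum-likelihood solve in a PCA-transformed space,
    validated leave-one-subject-out across nine microphone combinations.
    Includes extraction of impact/active peaks, loading rates, vertical impulse
    and foot-strike classification, curve-similarity and group statistics, and
    a synthetic cohort generator with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
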