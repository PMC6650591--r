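Package: corticotrack
Title: Speech-Brain Coupling, Hemispheric Asymmetry and Synthetic Entrainment Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of cortical tracking of the speech envelope from
    source-level electrophysiological time series: phase-locking value (PLV)
    against the stimulus envelope, hemispheric asymmetry index, weighted
    phase lag index (wPLI) and debiased wPLI connectivity, trial-wise
    spectral coherence with Fisher z transform, and the cohort-level
    nonparametric statistics used with them. Includes a synthetic-cohort
    simulator in which a right-hemisphere channel is a noisy phase
    oscillator entrained to the syllable-rate envelope (Arnold-tongue
    dynamics) while a left-hemisphere channel follows the envelope through
    a top-down gain, so that rate-tuning, connectivity-asymmetry and
    condition-contrast analyses can be exercised end to end with ground
    truth available for parameter-recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
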