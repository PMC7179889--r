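Package: arousaltrack
Title: Sympathetic Arousal Tracking from Skin Conductance and Heartbeats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracks a latent sympathetic-arousal state from mixed physiological
    observations: a binary skin-conductance-response event series, two
    continuous skin-conductance features (tonic level and a phasic-derived
    amplitude signal), and heartbeats treated as a binary point process with a
    history-dependent inverse Gaussian conditional intensity. Provides
    Gaussian-approximate Bayesian forward filtering with a Newton update,
    fixed-interval smoothing, closed-form and numerical M-steps inside an
    expectation-maximization loop, time-rescaling goodness-of-fit, a
    model-faithful simulator for parameter-recovery studies, skin-conductance
    preprocessing (lowpass/resample, tonic-phasic decomposition, SCR
    detection), and event-locked trial analysis for fear-conditioning
    paradigms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
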