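Package: avmsi
Title: Stimulus-Reconstruction Decoding of Attention and Audiovisual
    Integration from EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Backward temporal-response-function (TRF) modelling of
    cortical speech-envelope tracking in multi-speaker audiovisual
    scenes. Fits ridge-regularised linear decoders that reconstruct the
    acoustic speech envelope from multichannel EEG across a grid of
    stimulus-response lags, with leave-one-trial-out selection of the
    ridge parameter. Quantifies multisensory integration with the
    additive-model criterion, comparing an audiovisual (AV) decoder
    against a summed-covariance (A+V) decoder, integrated over lags or
    resolved lag by lag. Includes acoustic envelope extraction
    (gammatone filterbank, Hilbert envelopes, broadband average), EEG
    conditioning (zero-phase band-pass, resampling, mastoid
    re-referencing, bad-channel detection, spherical-spline
    interpolation), permutation null distributions, Wilcoxon and
    FDR inference, d-prime scoring of behavioural target detection,
    gaze-effect linear mixed-effects models with likelihood-ratio
    tests, and a synthetic cohort generator implementing a linear
    convolutional forward model with a switchable nonlinear
    audiovisual interaction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
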