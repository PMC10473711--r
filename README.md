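# avmsi

Stimulus-reconstruction decoding of attention and audiovisual
integration from EEG.

In multi-speaker ("cocktail party") listening, cortical activity tracks
the slow amplitude envelope of attended speech, and seeing the
speaker's face changes how strongly. `avmsi` is for researchers who
analyse that phenomenon with backward temporal response functions
(TRFs): it fits ridge-regularised linear decoders that reconstruct the
speech envelope `s(t)` from multichannel EEG across a window of
stimulus-response lags,

    s_hat(t) = sum_n sum_tau r_n(t + tau) g(tau, n),
    g = (R'R + lambda I)^(-1) R's,

with leave-one-trial-out selection of the ridge parameter over
10^-6, 10^-4, ..., 10^30, and quantifies multisensory integration with
the additive-model criterion

    MSI = mean_r(AV decoder) - mean_r(A+V decoder)

on congruent audiovisual trials, where the (A+V) decoder is built from
the summed normal-equation covariances of audio-only and visual-only
trials — the model of two independent unisensory processes. Both the
integrated 0–500 ms window and lag-resolved profiles (65 single-lag
decoders from −500 to +500 ms, 15.625 ms apart) are supported, along
with:

* acoustic envelope extraction (128-band gammatone filterbank,
  100–6500 Hz, Hilbert envelopes, broadband average, resampling to
  64 Hz, z-scoring) and minimal PCM WAV I/O;
* EEG conditioning (zero-phase 0.3–30 Hz band-pass, resampling, mastoid
  re-referencing, variance/kurtosis/probability bad-channel detection,
  spherical-spline interpolation, z-scoring);
* permutation null distributions (stimulus–EEG pair shuffling with the
  full cross-validated refit per shuffle), Wilcoxon signed-rank and
  rank-sum tests, Benjamini–Hochberg FDR;
* behavioural d′ scoring (2 s glitch / 4 s slow-motion response
  windows) and comprehension-vs-chance tests;
* gaze-effect linear mixed-effects models (ML random-intercept fits,
  likelihood-ratio tests, lag-resolved variants);
* a synthetic cohort generator implementing a linear convolutional
  forward model with attention gain, gaze-gated visual fidelity, and a
  switchable nonlinear audiovisual interaction (`kappa = 0` is the
  additive null), so the whole chain is testable without human data.

## Worked example

```r
library(avmsi)

fm  <- forward_model(n_channels = 32, noise_sd = 8, seed = 1)
sub <- simulate_subject(1, fm, seed = 1, trials_per_cell = 6,
                        duration_s = 30)
sub
#> Synthetic subject (experiment 1): 18 trials, 32 channels, fs 64 Hz
#>         gaze
#> modality c
#>       A  6
#>       AV 6
#>       V  6

dec <- fit_condition_decoder(sub, "AV", "attended", "c",
                             lags = lag_grid(0, 400),
                             lambda_grid = 10^c(0, 2, 4))
dec
#> Backward envelope decoder [AV] (AV_c_attended)
#>   32 channels x 27 lags (0..400 ms at 64 Hz), lambda = 1e+04
#>   cross-validated on 6 trials: mean held-out r = 0.2915

subject_msi(sub, "attended", "c", lag_grid(0, 400), 10^c(0, 2, 4))
#> MSI = r_AV - r_(A+V) = 0.2915 - 0.2560 = +0.0354 (6 trials)

ev <- simulate_behavior(sub$schedule, dprime_target = 2.5,
                       fa_rate = 0.05, seed = 1)
dprime(ev, "glitch")
#> d' = 3.155 (hit rate 0.840 over 25 targets, FA rate 0.015 over 65 windows)
```

The decoder print shows the mean held-out Pearson correlation between
the reconstructed and actual envelope (0.29 here — the generator's
default noise places single-trial attended accuracy in the empirically
realistic 0.1–0.3 range). The MSI line is the additive-model index: the
AV decoder outperforms the summed-covariance decoder by +0.035 on this
subject. The d′ line scores planted behavioural targets with the
2-second glitch response window.

`run_full(run_config(...))` orchestrates the whole two-experiment
workflow (24-decoder inventory, MSI tables, behavioural scoring, gaze
LMEs) and writes CSV artifacts stamped with a configuration hash;
`write_container()`/`validate_container()` handle the plain-text trial
container.

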