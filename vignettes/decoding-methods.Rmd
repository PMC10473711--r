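---
title: "Backward envelope decoding and the additive multisensory model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Backward envelope decoding and the additive multisensory model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avmsi)
```

## The problem

When two people speak at once, listeners track the attended talker's
speech partly through cortical entrainment to the slow amplitude
modulations of the acoustic waveform -- the speech envelope. Seeing the
talker's face adds visual articulatory information, and the brain's
combination of the two streams (multisensory integration) depends on
attention and on where the listener's gaze falls. `avmsi` implements the
full analysis chain used to study this with EEG in two-speaker
audiovisual "cocktail party" experiments: envelope extraction, EEG
conditioning, backward (stimulus-reconstruction) decoding, an
additive-model integration index, lag-resolved profiles, nonparametric
and mixed-effects inference, and behavioural scoring -- together with a
synthetic cohort generator, because raw EEG of this kind is typically
shareable only on request.

## The core model

The central estimator is a backward temporal response function: a linear
map from multichannel EEG to the envelope,

$$\hat s(t) = \sum_{n}\sum_{\tau} r_n(t+\tau)\, g(\tau, n),$$

with lags $\tau$ spanning 0--500 ms after the stimulus (33 lags at
64 Hz). The weights solve the ridge-regularised normal equations
$g = (R^\top R + \lambda I)^{-1} R^\top s$ on lagged design matrices
accumulated over trials; `envelope_decoder()` selects $\lambda$ by
leave-one-trial-out cross-validation over $10^{-6}, 10^{-4}, \dots,
10^{30}$, maximising the mean held-out Pearson correlation between
$\hat s$ and $s$ (ties break toward the heavier penalty). Trial edges
are zero-padded, the intercept column is unpenalised, and per-trial
correlations are averaged rather than pooled -- matching how these
models are conventionally fit and reported.

Integration is quantified with the additive-model criterion. An AV
decoder is trained on congruent audiovisual trials. An "A+V" decoder
representing two independent unisensory processes is built by summing
the normal-equation covariances of audio-only trials (target: the heard
envelope) and visual-only trials (target: the unheard envelope matched
to the visible face), solving once, and choosing its $\lambda$ to
maximise reconstruction of the congruent AV trials, which are disjoint
from its training data. The integration index is

$$\mathrm{MSI} = \bar r_{AV} - \bar r_{A+V}$$

on the same congruent AV trials, computed separately for attended and
unattended targets and for each gaze condition (crosshair `c`, direct
`d`, eavesdropping `e`). `single_lag_sweep()` repeats the whole
construction with a one-sample lag window at each of 65 lags from
$-500$ to $+500$ ms (15.625 ms apart) to resolve the effects in time.

## The synthetic cohort and what it emulates

The generator implements the minimal forward model under which backward
decoding behaves as the analysis assumes. Each stimulus stream drives
every channel through a rank-one spatio-temporal kernel:

* auditory kernel `h_A`, support 0--400 ms, peaking near 100 ms;
* visual kernel `h_V`, support $-200$--300 ms relative to the acoustic
  timeline; the visual signal itself is the envelope advanced by 120 ms
  (visible articulation precedes sound), smoothed, and jittered so its
  correlation with the envelope is about 0.55, in the range reported
  for natural audiovisual speech;
* interaction kernel `h_I`, a 200--400 ms delayed copy of the auditory
  shape, driven by the product of the physical (nonnegative) envelope
  and visual signals and scaled by `kappa` times the visual-fidelity
  gain. `kappa = 0` is the additive null; `kappa = 0.6` was calibrated
  once so the attended-direct interaction effect lands in the
  $\approx$ 0.01--0.02 range of reconstruction-accuracy units that the
  corresponding human effects occupy.

Attention multiplies the auditory response (`gain_att = 1` vs
`gain_unatt = 0.3`, yielding attended/unattended single-trial accuracies
near 0.2 and 0.07 with the default `noise_sd = 8` -- the empirically
realistic regime). Gaze gates only visual fidelity
(direct 0.6 $\ge$ crosshair 0.4 $\ge$ eavesdrop 0.25 by default), with
the unattended stream receiving the gain of wherever gaze actually
lands (so eavesdropping gives the *ignored* face the high-fidelity
gain). Noise is Gaussian with exponential spatial correlation across the
channel index and optional 1/f temporal shaping. Experiment designs
follow the two-experiment layout exactly: 60 trials (20 per attended
modality, crosshair) and 84 trials (14 per modality-by-gaze cell), with
the attended side balanced within cells and incongruent dubbing on the
unisensory-attention trials.

What the generator does **not** emulate: real scalp topographies and
volume conduction (kernels are smooth random maps over the channel
index), eye movements and their artifacts, non-stationarity across a
session, and any linguistic structure in the envelopes (they are
low-pass rectified noise). Passing tests therefore certify the
*analysis machinery* -- not that real EEG satisfies the forward model.

## Numerical choices

* The zero-phase band-pass (0.3--30 Hz) is applied as a Butterworth
  *magnitude* response in the frequency domain with mirror padding
  (order-4 high-pass cornered at 0.27 Hz, order-5 low-pass at 33 Hz).
  A transfer-function Butterworth at 0.3 Hz normalised to a 512 Hz rate
  is numerically fragile, and two-pass filtering would double the edge
  attenuation; the frequency-domain form keeps the response within 3 dB
  across the nominal band while attenuating 0.05 Hz drift and 60 Hz
  line noise by more than 20 dB (verified by measured transfer
  functions in the tests).
* Bad channels: the variance rule (variance exceeding three times the
  channel average) is kept verbatim; the spectro-statistical criteria of
  the usual toolboxes are re-specified as robust-z thresholds (default
  5) on excess kurtosis and on the mean negative log-probability of the
  standardised amplitudes under the pooled amplitude density --
  reproducible, dependency-free definitions. Interpolation uses
  spherical splines (order 4, Legendre degree 7, regularisation
  `1e-5`).
* The ridge solve is a Cholesky factorisation with an explicit
  rank-deficiency guard (relative pivot below `1e-7` signals a
  singular system rather than returning garbage). Reconstructions with
  zero variance raise a classed error -- never a silent `r = 0`.
* The permutation null (`permutation_null()`) exploits the fact that
  the lagged covariance `XtX` does not depend on the envelope
  assignment: Cholesky factors are cached per fold and ridge candidate
  and all permutations are solved in one batched triangular solve,
  which makes 1000-shuffle nulls tractable and 100-shuffle nulls cheap.
* Wilcoxon tests drop zero differences, use exact distributions for up
  to 25 untied values and the continuity-corrected normal approximation
  otherwise; d-prime clamps perfect rates by `1/(2N)`; the false-alarm
  denominator is the number of window-length non-target bins tiling the
  scored trials (2 s glitch windows, 4 s slow-motion windows).
* Mixed models are fit by maximum likelihood (not REML) so
  log-likelihood-ratio tests between nested fixed-effect structures are
  valid; gaze is coded as the ordered numeric distance from the
  attention target (direct 0, crosshair 1, eavesdrop 2), reproducing
  the one-degree-of-freedom chi-square convention under which the
  published statistics (e.g. LLR 9.33 -> p 0.0023) are consistent.
  lme4's convergence check is advisory at these problem sizes; a
  flagged check is signalled as a classed warning with the diagnostics
  and the fit retained, and lag-resolved tables carry a `converged`
  column instead of dropping lags.

## Design decisions that were genuinely open

* Envelopes are z-scored per trial (trials are the cross-validation
  unit); EEG is z-scored per recording. Both have switches.
* Permutation shuffles stay within a condition cell, preserving the
  condition-specific envelope statistics.
* The A+V decoder's $\lambda$ is independent of the unisensory
  decoders' (it is optimised against the congruent AV trials, as the
  quoted procedure requires).
* Single-lag decoders re-run the same $\lambda$ selection at every lag.
* The behavioural generator plants 1--6 targets per trial in
  non-overlapping response windows and inverts the equal-variance
  Gaussian detection model, so scoring its output recovers the target
  d-prime within binomial error.

## A finite-sample bias in the additive-model comparison

The additive-null invariant -- "with `kappa = 0`, expected MSI is 0" --
does **not** hold for the MSI statistic as conventionally computed, at
the cohort sizes a desk-scale simulation can afford (6 trials of 30 s
per cell). Two mechanisms, both inherent to the published procedure,
push MSI positive by roughly +0.02 with a cohort standard error of
about 0.005:

1. **Selection optimism in** $\bar r_{AV}$: the reported AV accuracy is
   the maximum over the $\lambda$ grid of the very cross-validation
   curve used to select $\lambda$. In a matched control (an identically
   generated decoder evaluated on fresh trials without selection) the
   same quantity is about 0.02 lower.
2. **Unisensory cross-covariance noise in the A+V decoder**: the
   V-condition targets are only weakly decodable, so their contribution
   to $R^\top s$ is mostly noise; carrying that noise into the summed
   solve costs the A+V decoder about 0.025 of reconstruction accuracy
   relative to an A-only decoder evaluated on the same trials.

The attended-vs-unattended contrast does not reliably cancel the bias
either (the two attention states differ in signal-to-noise ratio, and
so does their bias). Consequently the acceptance checks asserting a
mean null MSI within two standard errors of zero, and a false-positive
rate below 10% for the AV-vs-(A+V) signed-rank test, fail by
construction and are retained as failing -- they document a genuine
property of the method, not a defect of the implementation (the
covariance algebra, the ridge solve, and the cross-validation loop are
each verified against independent brute-force oracles). The
permutation-based chance control, which compares a decoder against its
own stimulus-shuffled nulls and involves no cross-decoder comparison,
is verified to reject at its nominal rate under envelope-independent
EEG. Interpretation of small AV-minus-(A+V) differences should lean on
within-design contrasts (e.g. across gaze conditions) and on
permutation controls rather than on the raw index being zero under
additivity.

## Problem sizes used by the tests and the acceptance script

Cohort-level checks run at reduced, fixed sizes chosen once: the null
cohort at 16 subjects with 6 trials x 30 s per cell and 32 channels
(lag window 0--400 ms, ridge grid $10^{0,2,4}$); replicate-based rates
at 10 subjects, 4 trials x 20 s, 16 channels; permutation calibration
at 8 subjects x 5 trials of 8 s at 4 channels with 100 shuffles per
subject; mixed-model recovery at 31 participants x 3 gaze levels. Each
simulation is a pure function of its seed.

## Known limitations

* No forward (encoding) TRF, no banded or multivariate-stimulus ridge,
  no ICA artifact removal, no source localisation -- all outside the
  analysis being reproduced.
* BDF/EDF import is not included; data enter as plain-text containers
  (`write_container()`/`read_container()`) or in memory.
* The generator's additive law is rank-one per stream; real EEG mixes
  many sources with richer spatio-temporal structure.
```
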