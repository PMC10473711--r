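#' Simulate a speech-like broadband envelope
#'
#' Stands in for the broadband acoustic envelope of natural running
#' speech: rectified Gaussian noise low-pass filtered at 8 Hz, so the
#' modulation energy is concentrated in the 1--8 Hz syllabic range,
#' clipped at zero and then z-scored.
#'
#' @param duration_s Trial duration in seconds (> 0).
#' @param fs Sampling rate in Hz (default 64).
#' @param seed Integer seed; the envelope is a pure function of
#'   `(duration_s, fs, seed)`.
#' @return Numeric vector of length `round(duration_s * fs)`, z-scored.
#' @examples
#' s <- simulate_envelope(60, seed = 1)
#' length(s)  # 3840
#' @export
simulate_envelope <- function(duration_s, fs = 64, seed = 1) {
  if (duration_s <= 0) stop2("bad_input", "duration_s must be > 0")
  if (fs <= 0) stop2("bad_input", "fs must be > 0")
  n <- round(duration_s * fs)
  with_seed(seed, {
    e <- fft_filter(abs(stats::rnorm(n)), fs = fs, hi = 8, n_hi = 4)
    zscore(pmax(e, 0))
  })
}

#' Derive a visual speech signal leading the acoustic envelope
#'
#' Visual articulation typically precedes the corresponding sound; this
#' returns a copy of the acoustic envelope advanced by `lead_ms`,
#' smoothed by a moving average of width `smooth_ms`, plus independent
#' Gaussian jitter, z-scored. Its cross-correlation with the source
#' envelope peaks at `-lead_ms`.
#'
#' @param envelope z-scored acoustic envelope (numeric vector).
#' @param lead_ms Visual lead in ms (>= 0, less than the trial length).
#' @param smooth_ms Moving-average width in ms (0 disables smoothing).
#' @param jitter_sd Jitter SD relative to the signal SD (0 disables).
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed for the jitter.
#' @return Numeric vector, same length as `envelope`, z-scored.
#' @export
simulate_visual_signal <- function(envelope, lead_ms = 120, smooth_ms = 50,
                                   jitter_sd = 0.1, fs = 64, seed = 1) {
  if (lead_ms < 0) stop2("bad_input", "lead_ms must be >= 0")
  k <- round(lead_ms * fs / 1000)
  n <- length(envelope)
  if (k >= n) stop2("bad_input", "lead longer than the trial")
  v <- shift_pad(envelope, -k)   # advance: v(t) = s(t + k)
  w <- round(smooth_ms * fs / 1000)
  if (w > 1) {
    v <- as.numeric(stats::filter(c(rep(v[1], w), v, rep(v[n], w)),
                                  rep(1 / w, w), sides = 2))[seq(w + 1, w + n)]
  }
  if (jitter_sd > 0) {
    v <- with_seed(seed, v + stats::rnorm(n, sd = jitter_sd * stats::sd(v)))
  }
  zscore(v)
}

## Convolve a stimulus with a rank-one kernel: channels x time matrix.
## y(t) = sum_k temporal[k] * stim(t - lag_k); negative lags give a
## response preceding the stimulus timeline (anticipatory visual drive).
kernel_response <- function(stim, kernel) {
  n <- length(stim)
  if (max(abs(kernel$lags)) >= n) {
    stop2("bad_input", "kernel support exceeds trial length")
  }
  y <- numeric(n)
  for (i in seq_along(kernel$lags)) {
    y <- y + kernel$temporal[i] * shift_pad(stim, kernel$lags[i])
  }
  outer(kernel$spatial, y)
}

## Spatially correlated (optionally 1/f-shaped) Gaussian channel noise.
channel_noise <- function(n_channels, n_samples, sd, spatial_corr, pink = FALSE) {
  z <- matrix(stats::rnorm(n_channels * n_samples), n_channels, n_samples)
  if (pink) {
    for (i in seq_len(n_channels)) {
      X <- stats::fft(z[i, ])
      f <- pmax(abs(c(seq(0, floor(n_samples / 2)),
                      seq(-ceiling(n_samples / 2) + 1, -1))), 1)
      x <- Re(stats::fft(X / sqrt(f), inverse = TRUE)) / n_samples
      z[i, ] <- x / stats::sd(x)
    }
  }
  if (spatial_corr > 0) {
    S <- spatial_corr^abs(outer(seq_len(n_channels), seq_len(n_channels), "-"))
    z <- t(chol(S)) %*% z
  }
  sd * z
}

#' Simulate one trial of multichannel EEG under the forward model
#'
#' The EEG is a sum of linear convolutional responses: the attended and
#' unattended heard audio envelopes through the auditory kernel (gains
#' `gain_att`, `gain_unatt`), the visible articulation signals through
#' the visual kernel (gain from `gain_visual_by_gaze`, resolved by which
#' stream the gaze lands on), plus -- only for congruent AV streams -- a
#' nonlinear interaction term `kappa * (h_I * (s . v))` driven by the
#' elementwise product of the audio envelope and its matched visual
#' signal, and spatially correlated Gaussian noise. Channels are
#' z-scored afterwards.
#'
#' Gaze resolves visual gains as: crosshair trials give both streams the
#' `crosshair` gain; direct-looking trials give the attended stream the
#' `direct` gain and the unattended stream the `eavesdrop` gain;
#' eavesdropping trials the reverse. The interaction amplitude is also
#' scaled by the same visual-fidelity gain, reflecting that integration
#' requires access to articulatory detail.
#'
#' @param row One row of a [make_schedule()] data.frame (fields
#'   `modality`, `gaze`, `congruent_att`, `congruent_unatt`).
#' @param streams List with `a_att` (required), and optionally `a_unatt`,
#'   `v_att`, `v_unatt`: heard audio envelopes and visual signals.
#' @param fm A [forward_model()].
#' @param keep_components If `TRUE`, attach the individual pre-noise
#'   component matrices as attribute `"components"` (used to assert the
#'   additive generative law).
#' @param seed Integer seed for the noise.
#' @return Channels x samples matrix of z-scored EEG.
#' @export
simulate_trial_eeg <- function(row, streams, fm, keep_components = FALSE,
                               seed = 1) {
  s_att <- streams$a_att
  if (is.null(s_att)) stop2("bad_input", "attended audio envelope required")
  n <- length(s_att)
  gv <- switch(as.character(row$gaze),
    c = fm$gain_visual_by_gaze[c("crosshair", "crosshair")],
    d = fm$gain_visual_by_gaze[c("direct", "eavesdrop")],
    e = fm$gain_visual_by_gaze[c("eavesdrop", "direct")],
    stop2("bad_input", "unknown gaze condition: %s", row$gaze))

  comp <- list(aud_att = fm$gain_att * kernel_response(s_att, fm$h_A))
  if (!is.null(streams$a_unatt) && fm$gain_unatt > 0) {
    comp$aud_unatt <- fm$gain_unatt * kernel_response(streams$a_unatt, fm$h_A)
  }
  if (!is.null(streams$v_att) && gv[1] > 0) {
    comp$vis_att <- gv[1] * kernel_response(streams$v_att, fm$h_V)
  }
  if (!is.null(streams$v_unatt) && gv[2] > 0) {
    comp$vis_unatt <- gv[2] * kernel_response(streams$v_unatt, fm$h_V)
  }
  ## Interaction drive: product of the physical (nonnegative) envelope
  ## and visual signals, so the multiplicative term carries
  ## envelope-correlated energy (the product of mean-zero signals would
  ## be nearly orthogonal to both factors).
  av_product <- function(s, v) zscore((s - min(s)) * (v - min(v)))
  if (fm$kappa > 0 && isTRUE(row$congruent_att) && !is.null(streams$v_att)) {
    comp$msi_att <- fm$kappa * gv[1] *
      kernel_response(av_product(s_att, streams$v_att), fm$h_I)
  }
  if (fm$kappa_unattended > 0 && isTRUE(row$congruent_unatt) &&
      !is.null(streams$a_unatt) && !is.null(streams$v_unatt)) {
    comp$msi_unatt <- fm$kappa_unattended * gv[2] *
      kernel_response(av_product(streams$a_unatt, streams$v_unatt), fm$h_I)
  }
  eeg <- Reduce(`+`, comp)
  if (fm$noise_sd > 0) {
    eeg <- eeg + with_seed(seed, channel_noise(fm$n_channels, n, fm$noise_sd,
                                               fm$noise_spatial_corr,
                                               fm$pink_noise))
  }
  out <- t(apply(eeg, 1, zscore, allow_constant = TRUE))
  if (keep_components) attr(out, "components") <- comp
  out
}

#' Simulate a full subject: schedule, stimuli, EEG
#'
#' Generates a trial schedule, independent attended/unattended speech
#' envelopes per trial (with separate unheard envelopes matched to the
#' visible faces on incongruent trials), leading visual signals, and
#' EEG through the forward model.
#'
#' @param experiment 1 or 2 (see [make_schedule()]).
#' @param fm A [forward_model()].
#' @param seed Integer seed; the subject is a pure function of its
#'   arguments.
#' @param trials_per_cell,duration_s Passed to [make_schedule()];
#'   defaults are the full designs (20/14 cells, 60 s trials).
#' @param lead_ms,smooth_ms,jitter_sd Passed to
#'   [simulate_visual_signal()].
#' @param keep_components Passed to [simulate_trial_eeg()].
#' @return Object of class `av_subject`: list with `schedule`, `trials`
#'   (each holding `eeg`, the four envelopes and two visual signals,
#'   plus condition labels), `fm`, `experiment`, `seed`.
#' @export
simulate_subject <- function(experiment, fm, seed = 1,
                             trials_per_cell = NULL, duration_s = 60,
                             lead_ms = 120, smooth_ms = 50, jitter_sd = 0.1,
                             keep_components = FALSE) {
  sch <- make_schedule(experiment, seed = seed,
                       trials_per_cell = trials_per_cell,
                       duration_s = duration_s)
  seeds <- with_seed(seed + 1, matrix(sample.int(.Machine$integer.max - 1,
                                                 nrow(sch) * 6), ncol = 6))
  trials <- lapply(seq_len(nrow(sch)), function(i) {
    row <- sch[i, ]
    a_att <- simulate_envelope(duration_s, fm$fs, seed = seeds[i, 1])
    a_unatt <- simulate_envelope(duration_s, fm$fs, seed = seeds[i, 2])
    f_att <- if (row$congruent_att) a_att else
      simulate_envelope(duration_s, fm$fs, seed = seeds[i, 3])
    f_unatt <- if (row$congruent_unatt) a_unatt else
      simulate_envelope(duration_s, fm$fs, seed = seeds[i, 4])
    v_att <- simulate_visual_signal(f_att, lead_ms, smooth_ms, jitter_sd,
                                    fm$fs, seed = seeds[i, 5])
    v_unatt <- simulate_visual_signal(f_unatt, lead_ms, smooth_ms, jitter_sd,
                                      fm$fs, seed = seeds[i, 6])
    eeg <- simulate_trial_eeg(row,
                              list(a_att = a_att, a_unatt = a_unatt,
                                   v_att = v_att, v_unatt = v_unatt),
                              fm, keep_components = keep_components,
                              seed = seeds[i, 1])
    list(eeg = eeg, env_audio_att = a_att, env_audio_unatt = a_unatt,
         env_face_att = f_att, env_face_unatt = f_unatt,
         vis_att = v_att, vis_unatt = v_unatt,
         modality = row$modality, gaze = row$gaze,
         congruent_att = row$congruent_att,
         congruent_unatt = row$congruent_unatt)
  })
  structure(list(schedule = sch, trials = trials, fm = fm,
                 experiment = experiment, seed = seed),
            class = "av_subject")
}

#' @export
print.av_subject <- function(x, ...) {
  cat(sprintf("Synthetic subject (experiment %d): %d trials, %d channels, fs %g Hz\n",
              x$experiment, length(x$trials), x$fm$n_channels, x$fm$fs))
  print(table(modality = x$schedule$modality, gaze = x$schedule$gaze))
  invisible(x)
}

#' Simulate a cohort of subjects
#'
#' Each subject receives its own forward-model kernels (fresh spatial
#' maps, i.e. individual anatomy) but shares all gain/noise parameters.
#'
#' @param n_subjects Number of subjects.
#' @param experiment 1 or 2.
#' @param seed Master seed; per-subject seeds are drawn from it.
#' @param fm_args List of arguments to [forward_model()] shared by all
#'   subjects (the per-subject `seed` is added automatically).
#' @param ... Passed to [simulate_subject()] (e.g. `trials_per_cell`,
#'   `duration_s`).
#' @return List of `av_subject` objects.
#' @export
simulate_cohort <- function(n_subjects, experiment, seed = 1,
                            fm_args = list(), ...) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, n_subjects))
  lapply(seq_len(n_subjects), function(i) {
    fm <- do.call(forward_model, c(fm_args, list(seed = seeds[i])))
    simulate_subject(experiment, fm, seed = seeds[i], ...)
  })
}

#' Simulate behavioural target and response streams
#'
#' Inverse of [dprime()]: plants 1--6 visual targets per trial with
#' visual task (glitches on AV trials, slow-motion events on V trials),
#' generates hits at the rate implied by `dprime_target` and `fa_rate`
#' under the equal-variance Gaussian model, places false alarms in the
#' non-target windows at `fa_rate`, and draws comprehension answers
#' (2 questions, 4 choices) at `comprehension_p` on trials with an audio
#' task. Response windows are 2 s for glitches and 4 s for slow-motion
#' onsets.
#'
#' @param schedule A [make_schedule()] data.frame.
#' @param dprime_target Target sensitivity d-prime.
#' @param fa_rate False-alarm rate per non-target window, in (0, 1).
#' @param comprehension_p Per-question probability correct.
#' @param seed Integer seed.
#' @return Object of class `av_events`: list with data.frames `targets`
#'   (`trial`, `time`, `kind`), `responses` (`trial`, `time`),
#'   `comprehension` (`trial`, `n_questions`, `n_correct`), plus
#'   `duration_s` and the schedule's modalities.
#' @export
simulate_behavior <- function(schedule, dprime_target = 2, fa_rate = 0.1,
                              comprehension_p = 0.7, seed = 1) {
  if (fa_rate <= 0 || fa_rate >= 1) stop2("bad_input", "fa_rate must be in (0, 1)")
  hit_p <- stats::pnorm(dprime_target + stats::qnorm(fa_rate))
  if (hit_p <= 1e-12 || hit_p >= 1 - 1e-12) {
    stop2("bad_input", "infeasible (dprime_target, fa_rate) pair")
  }
  dur <- schedule$duration_s[1]
  with_seed(seed, {
    tg <- list(); rs <- list(); qa <- list()
    for (i in seq_len(nrow(schedule))) {
      mod <- schedule$modality[i]
      if (mod %in% c("AV", "V")) {
        kind <- if (mod == "AV") "glitch" else "slowmotion"
        w <- if (kind == "glitch") 2 else 4
        n_slots <- floor(dur / w)
        n_t <- sample(seq_len(min(6, n_slots - 1)), 1)
        slots <- sort(sample.int(n_slots, n_t)) - 1L
        times <- slots * w
        tg[[length(tg) + 1]] <- data.frame(trial = i, time = times, kind = kind)
        hit <- stats::runif(n_t) < hit_p
        if (any(hit)) {
          rs[[length(rs) + 1]] <- data.frame(
            trial = i, time = times[hit] + stats::runif(sum(hit), 0, w * 0.95))
        }
        open <- setdiff(seq_len(n_slots) - 1L, slots)
        fa <- open[stats::runif(length(open)) < fa_rate]
        if (length(fa)) {
          rs[[length(rs) + 1]] <- data.frame(
            trial = i, time = fa * w + stats::runif(length(fa), 0, w * 0.95))
        }
      }
      if (mod %in% c("AV", "A")) {
        qa[[length(qa) + 1]] <- data.frame(
          trial = i, n_questions = 2,
          n_correct = stats::rbinom(1, 2, comprehension_p))
      }
    }
    structure(list(
      targets = if (length(tg)) do.call(rbind, tg) else
        data.frame(trial = integer(), time = numeric(), kind = character()),
      responses = if (length(rs)) do.call(rbind, rs) else
        data.frame(trial = integer(), time = numeric()),
      comprehension = if (length(qa)) do.call(rbind, qa) else
        data.frame(trial = integer(), n_questions = integer(),
                   n_correct = integer()),
      duration_s = dur, modality = schedule$modality
    ), class = "av_events")
  })
}
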