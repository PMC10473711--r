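#' Linear convolutional forward model for synthetic cortical envelope tracking
#'
#' The generator's EEG law is the minimal linear-convolutional model
#' under which backward (stimulus-reconstruction) decoding behaves as
#' the analysis assumes: each stimulus stream drives every channel
#' through a rank-one spatio-temporal kernel, attention scales the
#' auditory response, gaze scales the visual response, and an optional
#' multiplicative audiovisual interaction term (strength `kappa`)
#' switches the additive null (`kappa = 0`) on or off.
#'
#' Kernels are stored as a lag axis (ms), a temporal profile and a
#' spatial (per-channel) map; the full channels-by-lags kernel is their
#' outer product. Defaults: an auditory kernel supported on 0--400 ms
#' peaking near 100 ms; a visual kernel supported on -200--300 ms
#' relative to the acoustic timeline (the visible articulation leads the
#' sound); an interaction kernel equal to a 200 ms-delayed copy of the
#' auditory kernel, motivated by late multisensory effects.
#'
#' @param n_channels Number of scalp channels (default 128).
#' @param n_mastoids Number of mastoid reference channels (default 2).
#' @param fs Sampling rate in Hz (default 64, the post-resampling EEG rate).
#' @param gain_att,gain_unatt Unitless auditory gains for the attended and
#'   unattended stream; must satisfy `gain_att > gain_unatt > 0`.
#' @param gain_visual_by_gaze Named numeric vector mapping gaze condition
#'   (`direct`, `crosshair`, `eavesdrop`) to the visual-fidelity gain of a
#'   gazed-at stream; must be non-increasing in that order and >= 0.
#' @param kappa Strength of the nonlinear audiovisual interaction applied
#'   to congruent attended AV streams; `kappa = 0` is the additive null.
#' @param kappa_unattended Interaction strength for the congruent
#'   unattended stream (default 0; the analysis makes no claim about
#'   obligatory integration of ignored speech).
#' @param noise_sd Standard deviation of the additive Gaussian channel
#'   noise, on the scale of the unit-norm kernels.
#' @param noise_spatial_corr Exponential spatial correlation of the noise
#'   across the channel index, in `[0, 1)`.
#' @param pink_noise Logical; if `TRUE` the noise is 1/f-shaped in time.
#' @param kernels Optional list with elements `h_A`, `h_V`, `h_I`, each as
#'   returned by [response_kernel()]; defaults are built from `seed`.
#' @param seed Integer seed fixing the kernel spatial maps.
#' @return An object of class `forward_model`.
#' @seealso [simulate_trial_eeg()], [simulate_subject()]
#' @export
forward_model <- function(n_channels = 128, n_mastoids = 2, fs = 64,
                          gain_att = 1, gain_unatt = 0.3,
                          gain_visual_by_gaze = c(direct = 0.8,
                                                  crosshair = 0.5,
                                                  eavesdrop = 0.25),
                          kappa = 0, kappa_unattended = 0,
                          noise_sd = 1, noise_spatial_corr = 0.5,
                          pink_noise = FALSE,
                          kernels = NULL, seed = 1) {
  if (!(gain_att > gain_unatt && gain_unatt >= 0)) {
    stop2("bad_input", "need gain_att > gain_unatt >= 0")
  }
  g <- gain_visual_by_gaze
  need <- c("direct", "crosshair", "eavesdrop")
  if (!all(need %in% names(g))) {
    stop2("bad_input", "gain_visual_by_gaze needs names %s",
          paste(need, collapse = ", "))
  }
  if (!(g["direct"] >= g["crosshair"] && g["crosshair"] >= g["eavesdrop"] &&
        g["eavesdrop"] >= 0)) {
    stop2("bad_input", "visual gains must satisfy direct >= crosshair >= eavesdrop >= 0")
  }
  if (noise_spatial_corr < 0 || noise_spatial_corr >= 1) {
    stop2("bad_input", "noise_spatial_corr must be in [0, 1)")
  }
  if (is.null(kernels)) {
    kernels <- with_seed(seed, list(
      h_A = response_kernel(fs, n_channels, support_ms = c(0, 400),
                            peak_ms = 100, shape = "gamma"),
      h_V = response_kernel(fs, n_channels, support_ms = c(-200, 300),
                            peak_ms = 0, shape = "cosine"),
      h_I = response_kernel(fs, n_channels, support_ms = c(200, 400),
                            peak_ms = 300, shape = "gamma")
    ))
  }
  for (k in kernels) {
    if (!all(is.finite(k$temporal)) || !all(is.finite(k$spatial))) {
      stop2("bad_input", "kernels must be finite")
    }
  }
  structure(list(
    n_channels = n_channels, n_mastoids = n_mastoids, fs = fs,
    gain_att = gain_att, gain_unatt = gain_unatt,
    gain_visual_by_gaze = g[need],
    kappa = kappa, kappa_unattended = kappa_unattended,
    noise_sd = noise_sd, noise_spatial_corr = noise_spatial_corr,
    pink_noise = pink_noise,
    h_A = kernels$h_A, h_V = kernels$h_V, h_I = kernels$h_I,
    seed = seed
  ), class = "forward_model")
}

#' Build a rank-one spatio-temporal response kernel
#'
#' The temporal profile is either a gamma-density bump (causal auditory
#' shape, peak at `peak_ms` within `support_ms`) or a raised cosine
#' centred on `peak_ms`; it is normalised to unit L2 norm. The spatial
#' map is a smooth unit-norm pattern over the channel index drawn from
#' the current RNG state (fix it with a seed through [forward_model()]).
#'
#' @param fs Sampling rate (Hz).
#' @param n_channels Number of channels the spatial map covers.
#' @param support_ms Length-2 numeric, kernel support in ms (may be
#'   negative: response preceding the stimulus timeline).
#' @param peak_ms Latency of the temporal peak in ms.
#' @param shape `"gamma"` or `"cosine"`.
#' @return List with `lags_ms`, `lags` (samples), `temporal`, `spatial`.
#' @export
response_kernel <- function(fs, n_channels, support_ms, peak_ms,
                            shape = c("gamma", "cosine")) {
  shape <- match.arg(shape)
  lags <- seq(round(support_ms[1] * fs / 1000), round(support_ms[2] * fs / 1000))
  t_ms <- lags * 1000 / fs
  temporal <- switch(shape,
    gamma = {
      x <- (t_ms - support_ms[1]) / 1000
      th <- max((peak_ms - support_ms[1]) / 1000 / 3, 1e-3)
      h <- (x / th)^3 * exp(3 - x / th)
      h
    },
    cosine = {
      w <- diff(support_ms)
      h <- 0.5 * (1 + cos(2 * pi * (t_ms - peak_ms) / w))
      h[abs(t_ms - peak_ms) > w / 2] <- 0
      h
    })
  temporal <- temporal / sqrt(sum(temporal^2))
  sp <- stats::filter(stats::rnorm(n_channels + 8), rep(1, 5), sides = 2)
  sp <- sp[!is.na(sp)][seq_len(n_channels)]
  spatial <- as.numeric(sp / sqrt(sum(sp^2)))
  list(lags_ms = t_ms, lags = lags, temporal = temporal, spatial = spatial)
}

#' @export
print.forward_model <- function(x, ...) {
  cat("Forward model for synthetic envelope-tracking EEG\n")
  cat(sprintf("  channels: %d scalp + %d mastoid, fs = %g Hz\n",
              x$n_channels, x$n_mastoids, x$fs))
  cat(sprintf("  auditory gain: attended %.3g, unattended %.3g\n",
              x$gain_att, x$gain_unatt))
  cat(sprintf("  visual gain by gaze: direct %.3g, crosshair %.3g, eavesdrop %.3g\n",
              x$gain_visual_by_gaze["direct"], x$gain_visual_by_gaze["crosshair"],
              x$gain_visual_by_gaze["eavesdrop"]))
  cat(sprintf("  interaction kappa: %.3g (unattended %.3g)%s\n", x$kappa,
              x$kappa_unattended,
              if (x$kappa == 0) " [additive null]" else ""))
  cat(sprintf("  noise sd %.3g, spatial corr %.2g\n", x$noise_sd,
              x$noise_spatial_corr))
  invisible(x)
}
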