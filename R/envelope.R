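#' Gammatone filterbank decomposition
#'
#' Decomposes an audio signal into logarithmically spaced frequency
#' bands with fourth-order gammatone filters, the standard model of
#' cochlear frequency analysis. Filtering is performed in the frequency
#' domain with the gammatone resonance response
#' `H(f) = (1 + i (f - fc)/b)^-4 + (1 + i (f + fc)/b)^-4`, where `b` is
#' the equivalent-rectangular-bandwidth (ERB) scale bandwidth
#' `1.019 * 24.7 * (4.37 fc / 1000 + 1)`. Centre frequencies are
#' log-spaced on `[f_lo, f_hi]` inclusive of both endpoints.
#'
#' @param audio Numeric vector of PCM samples.
#' @param fs Audio sampling rate in Hz (band edges must be below
#'   Nyquist).
#' @param n_bands Number of bands (default 128).
#' @param f_lo,f_hi Band-edge centre frequencies in Hz (defaults 100 and
#'   6500).
#' @return Samples x bands matrix of band-filtered signals, with the
#'   centre frequencies in attribute `"cf"`.
#' @export
gammatone_filterbank <- function(audio, fs, n_bands = 128, f_lo = 100,
                                 f_hi = 6500) {
  if (n_bands < 1) stop2("bad_input", "n_bands must be >= 1")
  if (!(f_lo < f_hi)) stop2("bad_input", "f_lo must be below f_hi")
  if (f_hi >= fs / 2) stop2("bad_input", "band edges must be below Nyquist")
  if (!all(is.finite(audio))) stop2("bad_input", "audio must be finite")
  cf <- exp(seq(log(f_lo), log(f_hi), length.out = n_bands))
  n <- length(audio)
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  X <- stats::fft(audio)
  out <- matrix(0, n, n_bands)
  for (k in seq_len(n_bands)) {
    b <- 1.019 * 24.7 * (4.37 * cf[k] / 1000 + 1)
    H <- (1 + 1i * (f - cf[k]) / b)^-4 + (1 + 1i * (f + cf[k]) / b)^-4
    out[, k] <- Re(stats::fft(X * H, inverse = TRUE)) / n
  }
  attr(out, "cf") <- cf
  out
}

#' Hilbert (analytic-signal) envelope
#'
#' The magnitude of the analytic signal obtained by one-sided spectrum
#' doubling; nonnegative by construction.
#'
#' @param band_signal Finite real numeric vector (nonempty).
#' @return Nonnegative envelope of the same length.
#' @export
hilbert_envelope <- function(band_signal) {
  if (!length(band_signal)) stop2("empty", "empty signal")
  if (!all(is.finite(band_signal))) stop2("bad_input", "signal must be finite")
  Mod(analytic_signal(band_signal))
}

#' Broadband envelope from narrowband envelopes
#'
#' Averages the narrowband envelopes across bands, low-pass filters the
#' average below the output Nyquist (32 Hz anti-alias cutoff at the
#' default 64 Hz output rate), resamples to `fs_out`, and z-scores.
#'
#' @param band_envelopes Samples x bands matrix (or single vector) of
#'   nonnegative narrowband envelopes at rate `fs_in`.
#' @param fs_in Input sampling rate (Hz).
#' @param fs_out Output rate (default 64 Hz, the EEG rate).
#' @return z-scored envelope of length `round(duration * fs_out)`.
#' @export
broadband_envelope <- function(band_envelopes, fs_in, fs_out = 64) {
  if (is.null(dim(band_envelopes))) {
    band_envelopes <- matrix(band_envelopes, ncol = 1)
  }
  if (!ncol(band_envelopes)) stop2("bad_input", "need >= 1 band")
  e <- rowMeans(band_envelopes)
  if (stats::sd(e) == 0) {
    stop2("degenerate", "silent input: envelope has zero variance")
  }
  e <- fft_filter(e, fs = fs_in, hi = fs_out / 2, n_hi = 6)
  n_out <- round(length(e) / fs_in * fs_out)
  t_in <- (seq_along(e) - 1) / fs_in
  t_out <- (seq_len(n_out) - 1) / fs_out
  zscore(stats::approx(t_in, e, xout = t_out, rule = 2)$y)
}

#' Broadband acoustic speech envelope at the EEG rate
#'
#' Full envelope-extraction pipeline: gammatone filterbank (128
#' log-spaced bands, 100--6500 Hz), Hilbert envelope per band, average
#' across bands, anti-aliased resampling to 64 Hz, z-score. The result
#' is invariant to positive rescaling of the input amplitude.
#'
#' @param audio Numeric vector of PCM samples (or the list returned by
#'   [read_wav()], in which case channels are averaged to mono).
#' @param fs Audio sampling rate in Hz (ignored when `audio` is a
#'   [read_wav()] list). Must be at least twice `f_hi`.
#' @param fs_out Output rate (default 64 Hz).
#' @param n_bands,f_lo,f_hi Passed to [gammatone_filterbank()].
#' @return z-scored envelope at `fs_out`.
#' @export
speech_envelope <- function(audio, fs = NULL, fs_out = 64, n_bands = 128,
                            f_lo = 100, f_hi = 6500) {
  if (is.list(audio)) {
    fs <- audio$fs
    audio <- rowMeans(audio$samples)
  }
  if (is.null(fs)) stop2("bad_input", "fs required")
  if (fs < 2 * f_hi) stop2("bad_input", "fs must be >= twice the upper band edge")
  bands <- gammatone_filterbank(audio, fs, n_bands, f_lo, f_hi)
  envs <- apply(bands, 2, hilbert_envelope)
  broadband_envelope(envs, fs_in = fs, fs_out = fs_out)
}
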