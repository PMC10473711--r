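## Internal numerical helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## z-score a vector; errors on zero variance unless `allow_constant`.
zscore <- function(x, allow_constant = FALSE) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    if (allow_constant) return(x - mean(x))
    stop2("degenerate", "cannot z-score a zero-variance signal")
  }
  (x - mean(x)) / s
}

## Classed error so callers can distinguish contract violations.
stop2 <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("avmsi_", class), "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

## Pearson correlation that signals degeneracy instead of returning NA.
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop2("mismatch", "signals differ in length")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || sx == 0 || !is.finite(sy) || sy == 0) {
    stop2("degenerate", "correlation undefined: constant signal")
  }
  stats::cor(x, y)
}

## Zero-phase frequency-domain filter with a Butterworth magnitude
## response. The signal is mirror-padded to suppress circular edge
## effects, transformed, multiplied by the real magnitude response
## (hence exactly zero phase), and truncated back.
##
## lo/hi are -3 dB-style corner frequencies in Hz (NULL to disable a
## side); n_lo/n_hi are the Butterworth orders of each side.
fft_filter <- function(x, fs, lo = NULL, hi = NULL, n_lo = 4, n_hi = 5) {
  n <- length(x)
  if (n < 4) return(x)
  pad <- min(n, max(16L, as.integer(3 * fs)))
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[seq(n - pad + 1L, n)]))
  m <- length(xp)
  f <- c(seq(0, floor(m / 2)), seq(-ceiling(m / 2) + 1, -1)) * fs / m
  fa <- abs(f)
  h <- rep(1, m)
  if (!is.null(lo) && lo > 0) {
    h <- h / sqrt(1 + ifelse(fa > 0, (lo / pmax(fa, 1e-12))^(2 * n_lo), Inf))
    h[fa == 0] <- 0
  }
  if (!is.null(hi)) h <- h / sqrt(1 + (fa / hi)^(2 * n_hi))
  y <- Re(stats::fft(stats::fft(xp) * h, inverse = TRUE)) / m
  y[seq(pad + 1L, pad + n)]
}

## Analytic signal via the FFT (one-sided spectrum doubling).
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0) stop2("empty", "empty signal")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

## Shift a vector by k samples (positive k delays), zero-padding.
shift_pad <- function(x, k) {
  n <- length(x)
  if (k == 0) return(x)
  if (abs(k) >= n) return(numeric(n))
  if (k > 0) c(numeric(k), x[seq_len(n - k)]) else c(x[seq(-k + 1, n)], numeric(-k))
}
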