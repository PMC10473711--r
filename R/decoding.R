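#' Integer lag grid for backward decoding
#'
#' Lags are expressed in ms relative to the stimulus and quantised to
#' the EEG sampling grid: positive lags use EEG occurring *after* the
#' stimulus sample. The canonical integrated window is 0--500 ms (33
#' lags at 64 Hz); the lag-resolved analysis sweeps -500--500 ms (65
#' single-sample grids at 15.625 ms spacing).
#'
#' @param tau_min_ms,tau_max_ms Lag window bounds in ms.
#' @param fs Sampling rate in Hz.
#' @return Object of class `lag_grid`: list with `tau_min_ms`,
#'   `tau_max_ms`, `fs`, integer `lags` (samples) and `lags_ms`.
#' @examples
#' length(lag_grid(0, 500)$lags)     # 33
#' length(lag_grid(-500, 500)$lags)  # 65
#' @export
lag_grid <- function(tau_min_ms, tau_max_ms, fs = 64) {
  if (tau_min_ms > tau_max_ms) stop2("bad_input", "tau_min_ms > tau_max_ms")
  lags <- seq(round(tau_min_ms * fs / 1000), round(tau_max_ms * fs / 1000))
  structure(list(tau_min_ms = tau_min_ms, tau_max_ms = tau_max_ms, fs = fs,
                 lags = as.integer(lags), lags_ms = lags * 1000 / fs),
            class = "lag_grid")
}

#' Build the lagged design matrix of a trial
#'
#' Row `t`, column `(lag L, channel n)` holds the EEG sample
#' `r_n(t + L)`, zero-padded outside the trial. Columns are grouped by
#' lag with channels varying fastest; an all-ones intercept column is
#' appended last.
#'
#' @param eeg Channels x samples matrix.
#' @param lags A [lag_grid()] or integer vector of sample lags.
#' @param intercept Append an intercept column (default `TRUE`).
#' @return Samples x (channels * lags + intercept) matrix.
#' @export
build_lagged_design <- function(eeg, lags, intercept = TRUE) {
  if (inherits(lags, "lag_grid")) lags <- lags$lags
  nt <- ncol(eeg); nc <- nrow(eeg)
  if (max(abs(lags)) >= nt) stop2("bad_input", "lag exceeds trial length")
  X <- matrix(0, nt, nc * length(lags) + as.integer(intercept))
  te <- t(eeg)
  for (j in seq_along(lags)) {
    L <- lags[j]
    cols <- (j - 1L) * nc + seq_len(nc)
    if (L >= 0) {
      X[seq_len(nt - L), cols] <- te[seq(L + 1L, nt), , drop = FALSE]
    } else {
      X[seq(-L + 1L, nt), cols] <- te[seq_len(nt + L), , drop = FALSE]
    }
  }
  if (intercept) X[, ncol(X)] <- 1
  X
}

#' Accumulate normal-equation covariances over trials
#'
#' Builds `XtX = sum_i R_i' R_i` and `Xty = sum_i R_i' s_i` over trials,
#' keeping the per-trial contributions so that leave-one-trial-out
#' training sets can be formed by subtraction. Accumulation is additive
#' and order-invariant, which is also what licenses the summed-
#' covariance (A+V) decoder.
#'
#' @param eegs List of channels x samples matrices.
#' @param envs List of target envelopes (one per trial).
#' @param lags A [lag_grid()].
#' @param intercept Include an unpenalised intercept column.
#' @return Object of class `cov_acc`: `XtX`, `Xty`, `n_samples`, and
#'   per-trial lists `XtX_i`, `Xty_i`.
#' @export
cov_accumulate <- function(eegs, envs, lags, intercept = TRUE) {
  stopifnot(length(eegs) == length(envs))
  XtX_i <- vector("list", length(eegs))
  Xty_i <- vector("list", length(eegs))
  n_samples <- 0L
  for (i in seq_along(eegs)) {
    if (ncol(eegs[[i]]) != length(envs[[i]])) {
      stop2("mismatch", "trial %d: EEG and envelope lengths differ", i)
    }
    X <- build_lagged_design(eegs[[i]], lags, intercept)
    XtX_i[[i]] <- crossprod(X)
    Xty_i[[i]] <- drop(crossprod(X, envs[[i]]))
    n_samples <- n_samples + nrow(X)
  }
  structure(list(XtX = Reduce(`+`, XtX_i), Xty = Reduce(`+`, Xty_i),
                 n_samples = n_samples, XtX_i = XtX_i, Xty_i = Xty_i,
                 intercept = intercept, n_trials = length(eegs)),
            class = "cov_acc")
}

## Merge accumulators (summed-covariance decoder); per-trial parts kept.
#' @export
`+.cov_acc` <- function(e1, e2) {
  stopifnot(inherits(e1, "cov_acc"), inherits(e2, "cov_acc"),
            identical(dim(e1$XtX), dim(e2$XtX)),
            identical(e1$intercept, e2$intercept))
  structure(list(XtX = e1$XtX + e2$XtX, Xty = e1$Xty + e2$Xty,
                 n_samples = e1$n_samples + e2$n_samples,
                 XtX_i = c(e1$XtX_i, e2$XtX_i),
                 Xty_i = c(e1$Xty_i, e2$Xty_i),
                 intercept = e1$intercept,
                 n_trials = e1$n_trials + e2$n_trials),
            class = "cov_acc")
}

## Low-level regularised normal-equation solve; the intercept column
## (last, when present) is left unpenalised.
ridge_solve <- function(XtX, Xty, lambda, intercept = TRUE) {
  if (lambda < 0) stop2("bad_input", "lambda must be >= 0")
  p <- ncol(XtX)
  pen <- rep(lambda, p)
  if (intercept) pen[p] <- 0
  ch <- tryCatch(chol(XtX + diag(pen, p)),
                 error = function(e) stop2("singular",
                   "normal equations singular at lambda = %g; raise lambda",
                   lambda))
  d <- diag(ch)
  if (min(d) <= 1e-7 * max(d)) {   # diag(chol) ~ sqrt(eigenvalue)
    stop2("singular", "normal equations singular at lambda = %g; raise lambda",
          lambda)
  }
  drop(backsolve(ch, backsolve(ch, Xty, transpose = TRUE)))
}

#' Solve the ridge normal equations of an accumulator
#'
#' Computes `g = (XtX + lambda * P)^-1 Xty` with `P` the identity except
#' for a zero in the intercept position, via a symmetric
#' positive-definite Cholesky solve. A singular system at `lambda = 0`
#' is signalled as an error of class `avmsi_singular`.
#'
#' @param acc A [cov_accumulate()] result.
#' @param lambda Ridge parameter (>= 0).
#' @return Numeric weight vector (channels x lags, + intercept last).
#' @export
solve_ridge <- function(acc, lambda) {
  stopifnot(inherits(acc, "cov_acc"))
  ridge_solve(acc$XtX, acc$Xty, lambda, acc$intercept)
}

#' Default ridge-parameter grid
#'
#' Powers of ten with exponents -6, -4, ..., 30 (19 candidates).
#' @return Numeric vector of length 19.
#' @export
default_lambda_grid <- function() 10^seq(-6, 30, by = 2)

#' Leave-one-trial-out selection of the ridge parameter
#'
#' For every candidate `lambda`, each trial is reconstructed by a
#' decoder trained on all other trials (formed by subtracting the
#' held-out trial's covariance contributions), and the per-trial Pearson
#' correlations with the target envelope are averaged. The winning
#' `lambda` maximises the mean held-out r; ties break toward the larger
#' (more regularised) value. Folds whose correlation is undefined
#' (constant reconstruction or target) are excluded with a warning; if
#' every fold is undefined the selection fails.
#'
#' @param eegs,envs,lags As in [cov_accumulate()].
#' @param lambda_grid Candidate ridge parameters.
#' @param acc Optional precomputed accumulator for these trials.
#' @return List: `lambda` (winner), `cv` (data.frame `lambda`,
#'   `mean_r`), `r_folds` (trials x lambdas matrix of held-out r).
#' @export
crossval_lambda <- function(eegs, envs, lags,
                            lambda_grid = default_lambda_grid(),
                            acc = NULL) {
  if (length(eegs) < 2) stop2("bad_input", "need >= 2 trials for cross-validation")
  if (is.null(acc)) acc <- cov_accumulate(eegs, envs, lags)
  nl <- length(lambda_grid)
  r <- matrix(NA_real_, acc$n_trials, nl)
  for (i in seq_len(acc$n_trials)) {
    Xi <- build_lagged_design(eegs[[i]], lags, acc$intercept)
    XtX_tr <- acc$XtX - acc$XtX_i[[i]]
    Xty_tr <- acc$Xty - acc$Xty_i[[i]]
    for (j in seq_len(nl)) {
      g <- ridge_solve(XtX_tr, Xty_tr, lambda_grid[j], acc$intercept)
      r[i, j] <- tryCatch(pearson_r(drop(Xi %*% g), envs[[i]]),
                          avmsi_degenerate = function(e) {
                            warning(sprintf(
                              "fold %d excluded at lambda %.3g: %s",
                              i, lambda_grid[j], conditionMessage(e)),
                              call. = FALSE)
                            NA_real_
                          })
    }
  }
  mean_r <- colMeans(r, na.rm = TRUE)
  if (all(is.nan(mean_r))) stop2("degenerate", "all cross-validation folds undefined")
  best <- max(lambda_grid[mean_r >= max(mean_r, na.rm = TRUE) - 1e-15])
  list(lambda = best, cv = data.frame(lambda = lambda_grid, mean_r = mean_r),
       r_folds = r)
}

#' Fit a backward ridge decoder reconstructing the speech envelope
#'
#' The central model of the package: a linear map from multichannel EEG
#' across a lag window to the acoustic speech envelope,
#' `s_hat(t) = sum_n sum_tau r_n(t + tau) g(tau, n)`, with `g` obtained
#' by ridge regression on the pooled trial covariances. When `lambda`
#' is `NULL` it is selected per fit by leave-one-trial-out
#' cross-validation over `lambda_grid`.
#'
#' @param eegs List of channels x samples EEG matrices (one per trial),
#'   or a single matrix.
#' @param envs List of target envelopes (or a single vector).
#' @param lags A [lag_grid()] (default 0--500 ms at 64 Hz).
#' @param lambda Ridge parameter; `NULL` to cross-validate.
#' @param lambda_grid Candidates for cross-validation.
#' @param kind Decoder label: `"AV"`, `"A"`, `"V"` or `"A+V"`.
#' @param condition Optional free-form condition label (e.g.
#'   `"AV_d_attended"`).
#' @return Object of class `envelope_decoder`: weights `g` as a
#'   lags x channels matrix plus intercept, the lag grid, `lambda`, the
#'   cross-validation table (`cv`, with held-out per-trial r in
#'   `r_folds`), and labels. Supports `print()`, `coef()`, `predict()`,
#'   `plot()` and [reconstruct()].
#' @examples
#' fm <- forward_model(n_channels = 8, noise_sd = 0.5, seed = 2)
#' sub <- simulate_subject(1, fm, seed = 2, trials_per_cell = 2,
#'                         duration_s = 10)
#' av <- sub$trials[sub$schedule$modality == "AV"]
#' dec <- envelope_decoder(lapply(av, `[[`, "eeg"),
#'                         lapply(av, `[[`, "env_audio_att"),
#'                         lag_grid(0, 250), lambda_grid = 10^c(0, 2, 4))
#' dec
#' @export
envelope_decoder <- function(eegs, envs, lags = lag_grid(0, 500),
                             lambda = NULL,
                             lambda_grid = default_lambda_grid(),
                             kind = "AV", condition = NULL) {
  if (is.matrix(eegs)) eegs <- list(eegs)
  if (is.numeric(envs)) envs <- list(envs)
  acc <- cov_accumulate(eegs, envs, lags)
  cv <- NULL
  if (is.null(lambda)) {
    if (length(lambda_grid) == 1 || length(eegs) < 2) {
      lambda <- lambda_grid[1]
    } else {
      sel <- crossval_lambda(eegs, envs, lags, lambda_grid, acc = acc)
      lambda <- sel$lambda
      cv <- sel
    }
  }
  g <- solve_ridge(acc, lambda)
  nc <- nrow(eegs[[1]])
  W <- matrix(g[seq_len(nc * length(lags$lags))], nrow = length(lags$lags),
              ncol = nc, byrow = TRUE)
  structure(list(weights = g,
                 weight_matrix = W,
                 intercept = if (acc$intercept) g[length(g)] else 0,
                 lags = lags, lambda = lambda,
                 cv = if (!is.null(cv)) cv$cv else NULL,
                 r_folds = if (!is.null(cv)) cv$r_folds else NULL,
                 kind = kind, condition = condition,
                 n_channels = nc, fs = lags$fs,
                 n_trials = length(eegs)),
            class = "envelope_decoder")
}

#' @export
print.envelope_decoder <- function(x, ...) {
  cat(sprintf("Backward envelope decoder [%s]%s\n", x$kind,
              if (!is.null(x$condition)) paste0(" (", x$condition, ")") else ""))
  cat(sprintf("  %d channels x %d lags (%g..%g ms at %g Hz), lambda = %.3g\n",
              x$n_channels, length(x$lags$lags), x$lags$tau_min_ms,
              x$lags$tau_max_ms, x$fs, x$lambda))
  if (!is.null(x$cv)) {
    cat(sprintf("  cross-validated on %d trials: mean held-out r = %.4f\n",
                x$n_trials, max(x$cv$mean_r, na.rm = TRUE)))
  } else {
    cat(sprintf("  fit on %d trial(s) at fixed lambda\n", x$n_trials))
  }
  invisible(x)
}

#' @export
coef.envelope_decoder <- function(object, ...) {
  W <- object$weight_matrix
  dimnames(W) <- list(lag_ms = format(object$lags$lags_ms),
                      channel = seq_len(object$n_channels))
  W
}

#' @describeIn envelope_decoder Reconstruct the envelope from new EEG;
#'   `newdata` is a channels x samples matrix (returns a vector) or a
#'   list of matrices (returns a list).
#' @param object,newdata,... Method arguments.
#' @export
predict.envelope_decoder <- function(object, newdata, ...) {
  one <- function(eeg) {
    X <- build_lagged_design(eeg, object$lags, intercept = TRUE)
    w <- object$weights
    if (length(w) == ncol(X) - 1L) w <- c(w, 0)
    drop(X %*% w)
  }
  if (is.matrix(newdata)) one(newdata) else lapply(newdata, one)
}

#' @export
summary.envelope_decoder <- function(object, ...) {
  print(object)
  w <- object$weight_matrix
  peak <- which(abs(w) == max(abs(w)), arr.ind = TRUE)[1, ]
  cat(sprintf("  peak |weight| %.4g at lag %.4g ms, channel %d\n",
              max(abs(w)), object$lags$lags_ms[peak[1]], peak[2]))
  invisible(object)
}

#' @export
plot.envelope_decoder <- function(x, ...) {
  w <- x$weight_matrix
  graphics::matplot(x$lags$lags_ms, w, type = "l", lty = 1,
                    col = grDevices::grey.colors(ncol(w), 0.1, 0.8),
                    xlab = "lag (ms)", ylab = "decoder weight",
                    main = sprintf("%s decoder weights", x$kind), ...)
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 3)
  invisible(x)
}

#' Reconstruct envelopes and score per-trial accuracy
#'
#' Applies a decoder to each trial and computes the per-trial Pearson
#' correlation between the reconstruction and the designated target
#' envelope. A constant reconstruction or target is signalled as an
#' error (class `avmsi_degenerate`), never silently scored 0.
#'
#' @param decoder An [envelope_decoder()].
#' @param eegs List of channels x samples matrices (or one matrix).
#' @param envs List of target envelopes (or one vector).
#' @param trial_ids Optional trial identifiers.
#' @return Object of class `av_reconstruction`: data.frame `scores`
#'   (`trial`, `r`), reconstructions `s_hat`, `mean_r`, decoder labels.
#' @export
reconstruct <- function(decoder, eegs, envs, trial_ids = NULL) {
  stopifnot(inherits(decoder, "envelope_decoder"))
  if (is.matrix(eegs)) eegs <- list(eegs)
  if (is.numeric(envs)) envs <- list(envs)
  stopifnot(length(eegs) == length(envs))
  if (is.null(trial_ids)) trial_ids <- seq_along(eegs)
  s_hat <- predict(decoder, eegs)
  r <- vapply(seq_along(eegs), function(i) pearson_r(s_hat[[i]], envs[[i]]),
              numeric(1))
  structure(list(scores = data.frame(trial = trial_ids, r = r),
                 s_hat = s_hat, mean_r = mean(r),
                 kind = decoder$kind, condition = decoder$condition),
            class = "av_reconstruction")
}

#' @export
print.av_reconstruction <- function(x, ...) {
  cat(sprintf("Reconstruction [%s]%s: %d trials, mean r = %.4f\n", x$kind,
              if (!is.null(x$condition)) paste0(" (", x$condition, ")") else "",
              nrow(x$scores), x$mean_r))
  invisible(x)
}

#' Fit the summed-covariance (A+V) decoder
#'
#' The additive-model reference decoder: covariances are accumulated
#' separately over audio-only trials (target: the heard envelope) and
#' visual-only trials (target: the unheard envelope matched to the
#' visible face), summed, and solved once — the decoder of two
#' independent unisensory processes. Its ridge parameter is chosen to
#' maximise the mean reconstruction accuracy of the *congruent AV*
#' trials, which are disjoint from its training data.
#'
#' @param eegs_A,envs_A Audio-only trials and their heard envelopes.
#' @param eegs_V,envs_V Visual-only trials and the unheard envelopes
#'   matched to the visible faces.
#' @param eegs_AV,envs_AV Congruent AV trials used for lambda selection
#'   and evaluation.
#' @param lags A [lag_grid()].
#' @param lambda Fixed ridge parameter; `NULL` to select over
#'   `lambda_grid`.
#' @param lambda_grid Candidate ridge parameters.
#' @return An [envelope_decoder()] of kind `"A+V"`, with the AV
#'   evaluation curve in `$cv`.
#' @export
fit_sum_decoder <- function(eegs_A, envs_A, eegs_V, envs_V,
                            eegs_AV, envs_AV, lags = lag_grid(0, 500),
                            lambda = NULL,
                            lambda_grid = default_lambda_grid()) {
  if (!length(eegs_A) || !length(eegs_V)) {
    stop2("bad_input", "both unisensory trial sets must be nonempty")
  }
  acc <- cov_accumulate(eegs_A, envs_A, lags) +
    cov_accumulate(eegs_V, envs_V, lags)
  cv <- NULL
  if (is.null(lambda)) {
    if (length(lambda_grid) == 1) {
      lambda <- lambda_grid[1]
    } else {
      r <- matrix(NA_real_, length(eegs_AV), length(lambda_grid))
      X_av <- lapply(eegs_AV, build_lagged_design, lags = lags)
      for (j in seq_along(lambda_grid)) {
        g <- solve_ridge(acc, lambda_grid[j])
        for (i in seq_along(eegs_AV)) {
          r[i, j] <- tryCatch(pearson_r(drop(X_av[[i]] %*% g), envs_AV[[i]]),
                              avmsi_degenerate = function(e) NA_real_)
        }
      }
      mean_r <- colMeans(r, na.rm = TRUE)
      lambda <- max(lambda_grid[mean_r >= max(mean_r, na.rm = TRUE) - 1e-15])
      cv <- list(cv = data.frame(lambda = lambda_grid, mean_r = mean_r),
                 r_folds = r)
    }
  }
  g <- solve_ridge(acc, lambda)
  nc <- nrow(eegs_A[[1]])
  W <- matrix(g[seq_len(nc * length(lags$lags))], nrow = length(lags$lags),
              ncol = nc, byrow = TRUE)
  structure(list(weights = g, weight_matrix = W,
                 intercept = g[length(g)],
                 lags = lags, lambda = lambda,
                 cv = if (!is.null(cv)) cv$cv else NULL,
                 r_folds = if (!is.null(cv)) cv$r_folds else NULL,
                 kind = "A+V", condition = NULL,
                 n_channels = nc, fs = lags$fs,
                 n_trials = acc$n_trials),
            class = "envelope_decoder")
}

## Condition cell selection helpers ------------------------------------

## Pull (eegs, envs) for a decoder kind x attention x gaze cell, with the
## target mapping of the decoder inventory: AV and A decoders target the
## heard audio envelope of their stream; V decoders target the unheard
## envelope matched to the stream's visible face.
condition_cell <- function(subject, kind, attention, gaze) {
  sch <- subject$schedule
  idx <- which(sch$modality == kind & sch$gaze == gaze)
  if (!length(idx)) {
    stop2("bad_input", "no trials in condition cell %s/%s", kind, gaze)
  }
  att <- attention == "attended"
  env_field <- if (kind == "V") {
    if (att) "env_face_att" else "env_face_unatt"
  } else {
    if (att) "env_audio_att" else "env_audio_unatt"
  }
  list(eegs = lapply(subject$trials[idx], `[[`, "eeg"),
       envs = lapply(subject$trials[idx], `[[`, env_field),
       trial_ids = idx)
}

#' Fit a decoder for one condition cell of a subject
#'
#' Selects the subject's trials with the given attended modality and
#' gaze and fits the corresponding decoder: `"AV"`, `"A"` and `"V"`
#' decoders are trained on their own condition's trials (targets per the
#' decoder inventory: heard audio for AV/A, unheard face-matched
#' envelope for V); `"sum"` builds the summed-covariance (A+V) decoder
#' from the A and V cells with lambda optimised against the congruent
#' AV cell.
#'
#' @param subject An `av_subject` (or compatible list with `schedule`
#'   and `trials`).
#' @param kind `"AV"`, `"A"`, `"V"` or `"sum"`.
#' @param attention `"attended"` or `"unattended"`: which stream's
#'   envelope is the regression target.
#' @param gaze `"c"`, `"d"` or `"e"`.
#' @param lags,lambda,lambda_grid As in [envelope_decoder()].
#' @return An [envelope_decoder()].
#' @export
fit_condition_decoder <- function(subject, kind = c("AV", "A", "V", "sum"),
                                  attention = c("attended", "unattended"),
                                  gaze = "c", lags = lag_grid(0, 500),
                                  lambda = NULL,
                                  lambda_grid = default_lambda_grid()) {
  kind <- match.arg(kind)
  attention <- match.arg(attention)
  label <- sprintf("%s_%s_%s", if (kind == "sum") "A+V" else kind, gaze,
                   attention)
  if (kind == "sum") {
    a <- condition_cell(subject, "A", attention, gaze)
    v <- condition_cell(subject, "V", attention, gaze)
    av <- condition_cell(subject, "AV", attention, gaze)
    dec <- fit_sum_decoder(a$eegs, a$envs, v$eegs, v$envs, av$eegs, av$envs,
                           lags, lambda, lambda_grid)
    dec$condition <- label
    dec
  } else {
    cell <- condition_cell(subject, kind, attention, gaze)
    envelope_decoder(cell$eegs, cell$envs, lags, lambda, lambda_grid,
                     kind = kind, condition = label)
  }
}

#' Fit the full decoder inventory for a yoked subject pair
#'
#' Fits the complete inventory used in the two-experiment analysis: 4
#' decoder kinds (AV, A, V, A+V) x 2 attentional states x 3 gaze
#' conditions = 24 decoders. Gaze `"c"` cells come from the experiment-1
#' subject, `"d"` and `"e"` cells from the experiment-2 subject.
#'
#' @param subject_exp1,subject_exp2 `av_subject` objects (or compatible
#'   recordings) from experiments 1 and 2.
#' @param lags,lambda,lambda_grid As in [envelope_decoder()].
#' @return Named list of 24 [envelope_decoder()]s, names like
#'   `"AV_d_attended"`.
#' @export
decoder_inventory <- function(subject_exp1, subject_exp2,
                              lags = lag_grid(0, 500), lambda = NULL,
                              lambda_grid = default_lambda_grid()) {
  out <- list()
  for (gaze in c("c", "d", "e")) {
    subject <- if (gaze == "c") subject_exp1 else subject_exp2
    for (attention in c("attended", "unattended")) {
      for (kind in c("AV", "A", "V", "sum")) {
        nm <- sprintf("%s_%s_%s", if (kind == "sum") "A+V" else kind,
                      gaze, attention)
        out[[nm]] <- fit_condition_decoder(subject, kind, attention, gaze,
                                           lags, lambda, lambda_grid)
      }
    }
  }
  out
}
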