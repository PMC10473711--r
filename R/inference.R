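#' Permutation null distribution of reconstruction accuracy
#'
#' Generates the chance-level distribution of the mean held-out
#' reconstruction accuracy by shuffling the stimulus-EEG pairing between
#' trials: each permutation reassigns the envelopes to the trials
#' uniformly at random, refits the decoder with the standard
#' leave-one-trial-out ridge-parameter selection, and records the mean
#' held-out Pearson r. The per-subject null summary used by the group
#' test is the mean of the `n_perm` null values.
#'
#' Because the lagged-covariance matrix `XtX` depends only on the EEG,
#' it is shared across permutations; only the cross-covariance with the
#' (re-assigned) envelope changes, so all permutations are solved
#' against cached Cholesky factors per fold and ridge candidate.
#'
#' @param eegs List of channels x samples matrices (>= 3 trials of equal
#'   length).
#' @param envs List of target envelopes.
#' @param lags A [lag_grid()].
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @param lambda_grid Ridge candidates for the per-permutation fits.
#' @return Object of class `av_null`: `null_r` (length `n_perm`),
#'   `null_mean`, `actual_r` (same pipeline under the identity
#'   assignment), `n_perm`, `seed`.
#' @export
permutation_null <- function(eegs, envs, lags, n_perm = 1000, seed = 1,
                             lambda_grid = default_lambda_grid()) {
  n <- length(eegs)
  if (n < 3) stop2("bad_input", "need >= 3 trials")
  if (n_perm < 1) stop2("bad_input", "n_perm must be >= 1")
  if (n_perm < 20) {
    warning("n_perm is very small; the group test will be poorly resolved",
            call. = FALSE)
  }
  len <- unique(vapply(envs, length, integer(1)))
  if (length(len) != 1) stop2("bad_input", "trials must have equal length")

  S <- do.call(cbind, envs)                       # samples x trials
  S_c <- sweep(S, 2, colMeans(S))
  S_sd <- apply(S, 2, stats::sd)
  perms <- with_seed(seed, {
    p <- replicate(n_perm, sample.int(n))
    matrix(p, nrow = n)
  })
  assign_mat <- cbind(seq_len(n), perms)          # col 1 = identity (actual)
  n_a <- ncol(assign_mat)
  nl <- length(lambda_grid)

  ## Per-trial design covariances and cross-covariances with every envelope.
  XtX_i <- vector("list", n); M_i <- vector("list", n)
  for (i in seq_len(n)) {
    X <- build_lagged_design(eegs[[i]], lags)
    XtX_i[[i]] <- crossprod(X)
    M_i[[i]] <- crossprod(X, S)                   # p x n
  }
  XtX <- Reduce(`+`, XtX_i)
  p <- ncol(XtX)
  ## Total Xty per assignment: p x n_a.
  Xty_tot <- matrix(0, p, n_a)
  for (i in seq_len(n)) Xty_tot <- Xty_tot + M_i[[i]][, assign_mat[i, ]]

  r <- array(NA_real_, c(n, nl, n_a))
  n_degenerate <- 0L
  for (i in seq_len(n)) {
    Xi <- build_lagged_design(eegs[[i]], lags)
    XtX_tr <- XtX - XtX_i[[i]]
    B <- Xty_tot - M_i[[i]][, assign_mat[i, ]]    # training Xty, p x n_a
    tgt <- assign_mat[i, ]
    Ec <- S_c[, tgt, drop = FALSE]
    Esd <- S_sd[tgt]
    for (j in seq_len(nl)) {
      pen <- rep(lambda_grid[j], p); pen[p] <- 0
      ch <- tryCatch(chol(XtX_tr + diag(pen, p)), error = function(e) NULL)
      if (is.null(ch)) next
      G <- backsolve(ch, backsolve(ch, B, transpose = TRUE))
      Shat <- Xi %*% G                            # samples x n_a
      sh_c <- sweep(Shat, 2, colMeans(Shat))
      sh_sd <- sqrt(colSums(sh_c^2) / (nrow(Shat) - 1))
      num <- colSums(sh_c * Ec) / (nrow(Shat) - 1)
      denom <- sh_sd * Esd
      ok <- denom > 0
      n_degenerate <- n_degenerate + sum(!ok)
      r[i, j, ok] <- num[ok] / denom[ok]
    }
  }
  if (n_degenerate > 0) {
    warning(sprintf("%d degenerate fold reconstructions excluded",
                    n_degenerate), call. = FALSE)
  }
  ## Per assignment: lambda maximising the mean fold r, then that mean.
  mean_by_lambda <- apply(r, c(2, 3), mean, na.rm = TRUE)   # nl x n_a
  pick <- function(k) {
    m <- mean_by_lambda[, k]
    if (all(is.nan(m))) return(NA_real_)
    max(m, na.rm = TRUE)
  }
  vals <- vapply(seq_len(n_a), pick, numeric(1))
  structure(list(null_r = vals[-1], null_mean = mean(vals[-1], na.rm = TRUE),
                 actual_r = vals[1], n_perm = n_perm, seed = seed),
            class = "av_null")
}

#' @export
print.av_null <- function(x, ...) {
  cat(sprintf("Permutation null (%d shuffles): null mean r = %.4f, actual r = %.4f\n",
              x$n_perm, x$null_mean, x$actual_r))
  invisible(x)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided paired test with the field's conventions: zero differences
#' are dropped, an exact distribution is used for n <= 25 untied
#' differences, and the normal approximation with continuity correction
#' otherwise. All-zero differences yield `p = 1` by contract.
#'
#' @param a,b Equal-length paired numeric vectors (`b` defaults to 0,
#'   i.e. a one-sample test of the differences).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List: `statistic` (V), `p`, `n` (nonzero pairs), `exact`.
#' @export
signed_rank <- function(a, b = 0, alternative = "two.sided") {
  if (length(b) == 1) b <- rep(b, length(a))
  if (length(a) != length(b)) stop2("mismatch", "paired vectors differ in length")
  d <- a - b
  d <- d[d != 0]
  if (!length(d)) return(list(statistic = 0, p = 1, n = 0L, exact = TRUE))
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(stats::wilcox.test(d, mu = 0, exact = exact,
                                            correct = TRUE,
                                            alternative = alternative))
  list(statistic = unname(wt$statistic), p = wt$p.value, n = length(d),
       exact = exact)
}

#' Wilcoxon rank-sum test for two independent groups
#'
#' Two-sided unpaired test with mid-rank treatment of ties; exact
#' distribution for small untied samples, normal approximation with
#' continuity correction otherwise.
#'
#' @param a,b Numeric vectors (both nonempty).
#' @param alternative As in [signed_rank()].
#' @return List: `statistic` (W), `p`, `exact`.
#' @export
rank_sum <- function(a, b, alternative = "two.sided") {
  if (!length(a) || !length(b)) stop2("bad_input", "both groups must be nonempty")
  if (length(unique(c(a, b))) == 1) {
    return(list(statistic = length(a) * length(b) / 2, p = 1, exact = FALSE))
  }
  exact <- length(a) <= 25 && length(b) <= 25 && !any(duplicated(c(a, b)))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE,
                                            alternative = alternative))
  list(statistic = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure over a family of p-values; used across the 65 lag
#' tests of the lag-resolved analyses.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param q Target FDR level (default 0.05).
#' @return List: `reject` (logical), `p_adj` (BH-adjusted p-values).
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (!length(pvals)) return(list(reject = logical(0), p_adj = numeric(0)))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop2("bad_input", "p-values must lie in [0, 1]")
  }
  p_adj <- stats::p.adjust(pvals, method = "BH")
  list(reject = !is.na(p_adj) & p_adj <= q, p_adj = p_adj)
}

#' Sensitivity (d-prime) scoring of visual target detection
#'
#' A response within 2 s of a glitch onset (AV trials) or 4 s of a
#' slow-motion onset (V trials) is a hit -- one response credited per
#' target; all other responses are false alarms. The false-alarm rate
#' denominator is the number of window-length non-target bins tiling the
#' scored trials. Perfect rates are corrected by `1/(2N)` before the
#' inverse-normal transform, and
#' `d' = qnorm(hit_rate) - qnorm(fa_rate)`.
#'
#' @param events An `av_events` object (see [simulate_behavior()]) or a
#'   compatible list with `targets`, `responses`, `duration_s`.
#' @param kind `"glitch"` or `"slowmotion"`; selects the target type and
#'   its response window.
#' @return Object of class `dprime_result`: `hits`, `misses`,
#'   `false_alarms`, `n_target_windows`, `n_nontarget_windows`,
#'   `hit_rate`, `fa_rate`, `dprime`.
#' @export
dprime <- function(events, kind = c("glitch", "slowmotion")) {
  kind <- match.arg(kind)
  w <- if (kind == "glitch") 2 else 4
  tg <- events$targets[events$targets$kind == kind, , drop = FALSE]
  if (!nrow(tg)) stop2("degenerate", "no %s targets: d-prime undefined", kind)
  trials <- unique(tg$trial)
  hits <- 0L; fas <- 0L
  for (tr in trials) {
    tt <- sort(tg$time[tg$trial == tr])
    rt <- sort(events$responses$time[events$responses$trial == tr])
    used <- rep(FALSE, length(tt))
    for (resp in rt) {
      ok <- which(!used & resp >= tt & resp <= tt + w)
      if (length(ok)) used[ok[1]] <- TRUE else fas <- fas + 1L
    }
    hits <- hits + sum(used)
  }
  n_t <- nrow(tg)
  n_nt <- sum(vapply(trials, function(tr) {
    k <- sum(tg$trial == tr)
    max(0, floor((events$duration_s - k * w) / w))
  }, numeric(1)))
  hr <- hits / n_t
  fr <- fas / n_nt
  clamp <- function(rate, n) min(max(rate, 1 / (2 * n)), 1 - 1 / (2 * n))
  hr_c <- clamp(hr, n_t); fr_c <- clamp(fr, n_nt)
  structure(list(hits = hits, misses = n_t - hits, false_alarms = fas,
                 n_target_windows = n_t, n_nontarget_windows = n_nt,
                 hit_rate = hr_c, fa_rate = fr_c,
                 dprime = stats::qnorm(hr_c) - stats::qnorm(fr_c)),
            class = "dprime_result")
}

#' @export
print.dprime_result <- function(x, ...) {
  cat(sprintf("d' = %.3f (hit rate %.3f over %d targets, FA rate %.3f over %d windows)\n",
              x$dprime, x$hit_rate, x$n_target_windows, x$fa_rate,
              x$n_nontarget_windows))
  invisible(x)
}

#' Test comprehension scores against chance
#'
#' One-sided Wilcoxon signed-rank test of per-subject mean comprehension
#' proportions against the 4-choice chance level of 0.25.
#'
#' @param scores Numeric vector of per-subject mean proportions correct.
#' @param chance Chance level (default 0.25).
#' @return List as from [signed_rank()], alternative `"greater"`.
#' @export
comprehension_test <- function(scores, chance = 0.25) {
  signed_rank(scores, chance, alternative = "greater")
}
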