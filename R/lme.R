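#' Fit a random-intercept linear mixed-effects model by maximum likelihood
#'
#' Gaussian LME with participant random intercepts, fit by ML (not
#' REML) so that nested fits can be compared with likelihood-ratio
#' tests. Gaze enters as an ordered numeric distance-from-target code
#' (direct = 0, crosshair = 1, eavesdrop = 2) so one coefficient
#' captures the monotone cost of gaze divergence.
#'
#' @param data data.frame with the response, fixed-effect columns and
#'   the grouping column.
#' @param response Name of the response column.
#' @param fixed Character vector of fixed-effect column names (default
#'   `c("gz", "exp")`); may be empty for an intercept-only (null) model.
#' @param group Name of the grouping column (default `"ptc"`).
#' @return Object of class `lme_fit`:
#' `beta`, `se`, `t`, `p` (Wald, with
#'   residual-df approximation), `logLik`, `n_obs`, `n_groups`,
#'   `singular` and `converged` flags, the fitted `lme4` model in
#'   `$model`, and the model specification (`response`, `fixed`,
#'   `group`). An optimizer
#'   convergence-check flag is signalled as a classed warning
#'   (`avmsi_nonconvergence`) with the diagnostics, and the fit is
#'   retained; a singular random-effect variance likewise warns.
#' @export
fit_lme <- function(data, response, fixed = c("gz", "exp"), group = "ptc") {
  if (!response %in% names(data)) stop2("bad_input", "missing response column")
  y <- data[[response]]
  if (!all(is.finite(y))) stop2("bad_input", "response must be finite")
  if (stats::var(y) == 0) stop2("degenerate", "constant response")
  if (length(unique(data[[group]])) < 2) stop2("bad_input", "need >= 2 groups")
  rhs <- paste(c(if (length(fixed)) fixed else "1",
                 sprintf("(1 | %s)", group)), collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  conv_msgs <- character(0)
  fit <- withCallingHandlers(
    suppressMessages(lme4::lmer(fml, data = data, REML = FALSE)),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
        conv_msgs <<- c(conv_msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    })
  if (length(conv_msgs)) {
    warning(structure(
      class = c("avmsi_nonconvergence", "warning", "condition"),
      list(message = sprintf("LME convergence check flagged: %s",
                             paste(conv_msgs, collapse = "; ")),
           call = sys.call(-1))))
  }
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning("singular random-effect variance; fit retained", call. = FALSE)
  }
  co <- summary(fit)$coefficients
  n <- nrow(data)
  df <- n - nrow(co)
  structure(list(beta = co[, "Estimate"], se = co[, "Std. Error"],
                 t = co[, "t value"],
                 p = 2 * stats::pt(-abs(co[, "t value"]), df),
                 logLik = as.numeric(stats::logLik(fit)),
                 n_obs = n, n_groups = length(unique(data[[group]])),
                 singular = singular, converged = !length(conv_msgs),
                 model = fit,
                 response = response, fixed = fixed, group = group),
            class = "lme_fit")
}

#' @export
print.lme_fit <- function(x, ...) {
  cat(sprintf("ML linear mixed-effects fit: %s ~ %s + (1 | %s)\n", x$response,
              if (length(x$fixed)) paste(x$fixed, collapse = " + ") else "1",
              x$group))
  tab <- data.frame(beta = x$beta, se = x$se, t = x$t, p = signif(x$p, 3))
  print(tab)
  cat(sprintf("logLik %.3f over %d obs, %d groups%s\n", x$logLik, x$n_obs,
              x$n_groups, if (x$singular) " [singular]" else ""))
  invisible(x)
}

#' Likelihood-ratio test of nested mixed-effects fits
#'
#' Twice the log-likelihood difference between a full and a reduced
#' ML fit on the same data, referred to a chi-square distribution with
#' degrees of freedom equal to the number of dropped fixed effects.
#'
#' @param fit_full,fit_reduced [fit_lme()] results; the reduced fixed
#'   effects must be a subset of the full ones, on identical data.
#' @return Object of class `llr_result`: `llr`, `df`, `p`.
#' @examples
#' # chi-square(1) upper tail at the LLR scale used throughout:
#' pchisq(9.33, df = 1, lower.tail = FALSE)   # ~0.0023
#' @export
llr_test <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "lme_fit"), inherits(fit_reduced, "lme_fit"))
  if (!identical(fit_full$response, fit_reduced$response) ||
      fit_full$n_obs != fit_reduced$n_obs) {
    stop2("bad_input", "fits must be on identical data")
  }
  if (!all(fit_reduced$fixed %in% fit_full$fixed)) {
    stop2("bad_input", "models are not nested")
  }
  df <- length(setdiff(fit_full$fixed, fit_reduced$fixed))
  llr <- 2 * (fit_full$logLik - fit_reduced$logLik)
  p <- if (df == 0) 1 else stats::pchisq(llr, df, lower.tail = FALSE)
  structure(list(llr = llr, df = df, p = p), class = "llr_result")
}

#' @export
print.llr_result <- function(x, ...) {
  cat(sprintf("LLR = %.3f, df = %d, p = %.3g\n", x$llr, x$df, x$p))
  invisible(x)
}

#' Lag-resolved mixed-effects modelling
#'
#' At every lag of a lag-resolved measure (e.g. `r_av` or `msi` profiles
#' stacked over subjects), fits the full model
#' `value ~ variable + controls + (1 | group)` against the reduced model
#' without `variable`, collects the coefficient of interest and the
#' likelihood-ratio test, and controls the false discovery rate across
#' lags by Benjamini-Hochberg. Lags whose fit fails to converge are
#' flagged, not dropped.
#'
#' @param data data.frame with columns `lag_ms`, `value`, the predictor
#'   columns and the grouping column.
#' @param variable Predictor of interest (default `"gz"`).
#' @param controls Control fixed effects (default `"exp"`).
#' @param group Grouping column (default `"ptc"`).
#' @param q FDR level across lags (default 0.05).
#' @return data.frame: `lag_ms`, `beta`, `se`, `p_wald`, `llr`, `p_llr`,
#'   `p_fdr`, `reject`, `converged` (one row per lag).
#' @export
timewise_lme <- function(data, variable = "gz", controls = "exp",
                         group = "ptc", q = 0.05) {
  lags <- sort(unique(data$lag_ms))
  rows <- lapply(lags, function(L) {
    d <- data[data$lag_ms == L, , drop = FALSE]
    res <- tryCatch({
      full <- suppressWarnings(fit_lme(d, "value", c(variable, controls),
                                       group))
      red <- suppressWarnings(fit_lme(d, "value", controls, group))
      lt <- llr_test(full, red)
      data.frame(lag_ms = L, beta = unname(full$beta[variable]),
                 se = unname(full$se[variable]),
                 p_wald = unname(full$p[variable]),
                 llr = lt$llr, p_llr = lt$p,
                 converged = full$converged && red$converged)
    }, error = function(e) {
      data.frame(lag_ms = L, beta = NA_real_, se = NA_real_,
                 p_wald = NA_real_, llr = NA_real_, p_llr = NA_real_,
                 converged = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  fdr <- fdr_bh(out$p_llr, q)
  out$p_fdr <- fdr$p_adj
  out$reject <- fdr$reject
  out
}

#' Relate trial-level comprehension to multisensory integration
#'
#' Mixed-effects model of trial-by-trial comprehension scores on the
#' corresponding multisensory-integration measure, with participant
#' random intercepts and an experiment control, against the reduced
#' model without the MSI term.
#'
#' @param trial_table data.frame with columns `comprehension`, `msi`,
#'   `exp`, `ptc`.
#' @return List: `fit` (full [fit_lme()]), `llr` ([llr_test()] vs the
#'   reduced model).
#' @export
comprehension_from_msi <- function(trial_table) {
  full <- fit_lme(trial_table, "comprehension", c("msi", "exp"), "ptc")
  red <- fit_lme(trial_table, "comprehension", "exp", "ptc")
  list(fit = full, llr = llr_test(full, red))
}
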