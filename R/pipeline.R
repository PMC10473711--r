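#' Configuration for a full analysis run
#'
#' Collects every tunable of the two-experiment workflow: the integrated
#' and single-lag windows, the ridge-exponent grid, permutation count,
#' FDR level, cohort sizes and generator arguments, and the master seed.
#' Defaults mirror the full study design (16 + 15 subjects with 7
#' shared, 20/14 trials per cell, 60 s trials, 128 channels, 1000
#' permutations); simulations at reduced scale override them explicitly.
#'
#' @param experiments Experiments to run (subset of `c(1, 2)`).
#' @param lag_window Integrated decoding window in ms (default 0--500).
#' @param single_lag_window Lag-resolved window in ms (default +/-500).
#' @param lambda_exponents Base-10 exponents of the ridge grid
#'   (default -6, -4, ..., 30).
#' @param n_perm Permutations for null distributions (0 disables).
#' @param fdr_q FDR level.
#' @param seed Master seed.
#' @param n_subjects_exp1,n_subjects_exp2,n_shared Cohort sizes and the
#'   number of participants appearing in both experiments.
#' @param trials_per_cell,duration_s Design overrides (NULL = full).
#' @param fm_args Arguments to [forward_model()] for the generator.
#' @return Object of class `run_config`.
#' @export
run_config <- function(experiments = c(1, 2),
                       lag_window = c(0, 500),
                       single_lag_window = c(-500, 500),
                       lambda_exponents = seq(-6, 30, 2),
                       n_perm = 1000, fdr_q = 0.05, seed = 1,
                       n_subjects_exp1 = 16, n_subjects_exp2 = 15,
                       n_shared = 7, trials_per_cell = NULL,
                       duration_s = 60, fm_args = list()) {
  cfg <- list(experiments = experiments, lag_window = lag_window,
              single_lag_window = single_lag_window,
              lambda_exponents = lambda_exponents, n_perm = n_perm,
              fdr_q = fdr_q, seed = seed,
              n_subjects_exp1 = n_subjects_exp1,
              n_subjects_exp2 = n_subjects_exp2,
              n_shared = min(n_shared, n_subjects_exp1, n_subjects_exp2),
              trials_per_cell = trials_per_cell, duration_s = duration_s,
              fm_args = fm_args)
  class(cfg) <- "run_config"
  cfg
}

#' Hash of a configuration
#'
#' MD5 of the deparsed configuration; embedded in every output file so
#' that runs are byte-comparable exactly when their configurations and
#' seeds agree.
#'
#' @param config A [run_config()].
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(unclass(config)), tf)
  unname(tools::md5sum(tf))
}

## Stage logger with wall-clock timing.
stage <- function(name, expr) {
  t0 <- Sys.time()
  message(sprintf("[%s] start", name))
  out <- force(expr)
  message(sprintf("[%s] done in %.1f s", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Write a subject's trial data as a plain-text container
#'
#' Directory layout: `attributes.csv` (fs, experiment, seed, channel
#'   count), `schedule.csv`, and per trial `trial_<k>_eeg.csv`
#'   (channels x samples) plus `trial_<k>_env.csv` with the four
#'   envelopes and two visual signals as columns.
#'
#' @param subject An `av_subject`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_container <- function(subject, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(
    key = c("fs", "experiment", "seed", "n_channels", "n_trials"),
    value = c(subject$fm$fs, subject$experiment, subject$seed,
              subject$fm$n_channels, length(subject$trials))),
    file.path(dir, "attributes.csv"), row.names = FALSE)
  utils::write.csv(subject$schedule, file.path(dir, "schedule.csv"),
                   row.names = FALSE)
  for (k in seq_along(subject$trials)) {
    tr <- subject$trials[[k]]
    utils::write.csv(as.data.frame(tr$eeg),
                     file.path(dir, sprintf("trial_%03d_eeg.csv", k)),
                     row.names = FALSE)
    utils::write.csv(data.frame(
      env_audio_att = tr$env_audio_att, env_audio_unatt = tr$env_audio_unatt,
      env_face_att = tr$env_face_att, env_face_unatt = tr$env_face_unatt,
      vis_att = tr$vis_att, vis_unatt = tr$vis_unatt),
      file.path(dir, sprintf("trial_%03d_env.csv", k)), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a plain-text trial container
#'
#' @param dir Directory written by [write_container()].
#' @return A list shaped like an `av_subject` (without the forward
#'   model), usable by the decoding functions.
#' @export
read_container <- function(dir) {
  att <- utils::read.csv(file.path(dir, "attributes.csv"))
  a <- function(k) as.numeric(att$value[att$key == k])
  sch <- utils::read.csv(file.path(dir, "schedule.csv"))
  trials <- lapply(seq_len(nrow(sch)), function(k) {
    eeg <- as.matrix(utils::read.csv(
      file.path(dir, sprintf("trial_%03d_eeg.csv", k))))
    dimnames(eeg) <- NULL
    env <- utils::read.csv(file.path(dir, sprintf("trial_%03d_env.csv", k)))
    c(list(eeg = eeg), as.list(env),
      list(modality = sch$modality[k], gaze = sch$gaze[k],
           congruent_att = sch$congruent_att[k],
           congruent_unatt = sch$congruent_unatt[k]))
  })
  structure(list(schedule = sch, trials = trials,
                 fm = list(fs = a("fs"), n_channels = a("n_channels")),
                 experiment = a("experiment"), seed = a("seed")),
            class = "av_subject")
}

#' Validate a trial container
#'
#' Checks trial counts against the schedule and the experiment's design
#' (60 trials for experiment 1, 84 for experiment 2, at full scale),
#' the sampling rate, condition-label completeness, and EEG/envelope
#' length agreement.
#'
#' @param dir Container directory.
#' @return List of class `container_report`: `ok` (logical), `issues`
#'   (character vector of schema violations, empty when clean).
#' @export
validate_container <- function(dir) {
  issues <- character(0)
  need <- file.path(dir, c("attributes.csv", "schedule.csv"))
  if (!all(file.exists(need))) {
    return(structure(list(ok = FALSE,
                          issues = "missing attributes.csv/schedule.csv"),
                     class = "container_report"))
  }
  att <- utils::read.csv(file.path(dir, "attributes.csv"))
  a <- function(k) as.numeric(att$value[att$key == k])
  sch <- utils::read.csv(file.path(dir, "schedule.csv"))
  if (a("fs") != 64) issues <- c(issues, sprintf("fs is %g, expected 64", a("fs")))
  if (nrow(sch) != a("n_trials")) {
    issues <- c(issues, "schedule row count disagrees with attributes")
  }
  full <- if (a("experiment") == 1) 60 else 84
  dur <- if ("duration_s" %in% names(sch)) sch$duration_s[1] else 60
  if (nrow(sch) != full && dur == 60) {
    issues <- c(issues, sprintf("experiment %g expects %d trials, found %d",
                                a("experiment"), full, nrow(sch)))
  }
  if (!all(c("modality", "gaze", "attended_side") %in% names(sch))) {
    issues <- c(issues, "schedule missing condition labels")
  }
  n_expected <- round(dur * a("fs"))
  for (k in seq_len(nrow(sch))) {
    fe <- file.path(dir, sprintf("trial_%03d_eeg.csv", k))
    fv <- file.path(dir, sprintf("trial_%03d_env.csv", k))
    if (!file.exists(fe) || !file.exists(fv)) {
      issues <- c(issues, sprintf("trial %d files missing", k))
      next
    }
    eeg <- utils::read.csv(fe, nrows = 1)
    env <- utils::read.csv(fv)
    if (ncol(eeg) != n_expected) {
      issues <- c(issues, sprintf("trial %d: EEG length %d != %d", k,
                                  ncol(eeg), n_expected))
    }
    if (nrow(env) != n_expected) {
      issues <- c(issues, sprintf("trial %d: envelope length %d != %d", k,
                                  nrow(env), n_expected))
    }
  }
  structure(list(ok = !length(issues), issues = issues),
            class = "container_report")
}

#' @export
print.container_report <- function(x, ...) {
  if (x$ok) cat("container OK\n") else {
    cat("container INVALID:\n")
    for (i in x$issues) cat(" -", i, "\n")
  }
  invisible(x)
}

## Write a CSV with a provenance header line ("# config <hash> seed <s>").
write_result_csv <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config %s seed %d", hash, seed), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Run the full synthetic two-experiment analysis
#'
#' Orchestrates every stage on generated cohorts: simulation, the
#' 24-decoder inventory (for the first yoked subject pair), per-subject
#' MSI and attentional benefit per gaze condition, behavioural d-prime
#' and comprehension scoring, and the combined-experiment gaze LMEs with
#' likelihood-ratio tests. Results are returned and, when `out_dir` is
#' given, written as CSV files stamped with the configuration hash and
#' seed (reruns with an equal hash are byte-comparable). With `resume =
#' TRUE`, stages whose output file already exists are skipped.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory for CSV artifacts.
#' @param resume Skip stages whose outputs exist (default `FALSE`).
#' @return List: `inventory` (24 decoders), `msi` (per subject x gaze x
#'   attention), `behavior`, `lme` (per-response fits and LLR tests),
#'   `config_hash`.
#' @export
run_full <- function(config = run_config(), out_dir = NULL, resume = FALSE) {
  hash <- config_hash(config)
  grid <- 10^config$lambda_exponents
  lags <- lag_grid(config$lag_window[1], config$lag_window[2])
  outfile <- function(nm) if (is.null(out_dir)) NULL else file.path(out_dir, nm)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  done <- function(nm) resume && !is.null(out_dir) &&
    file.exists(file.path(out_dir, nm))

  cohorts <- stage("simulate", {
    seeds <- with_seed(config$seed, sample.int(.Machine$integer.max - 1,
                       config$n_subjects_exp1 + config$n_subjects_exp2))
    ## Shared participants reuse their experiment-1 seed (same kernels).
    s1 <- seeds[seq_len(config$n_subjects_exp1)]
    s2 <- c(s1[seq_len(config$n_shared)],
            seeds[config$n_subjects_exp1 +
                    seq_len(config$n_subjects_exp2 - config$n_shared)])
    make <- function(exp_id, s) lapply(s, function(si) {
      fm <- do.call(forward_model, c(config$fm_args, list(seed = si)))
      simulate_subject(exp_id, fm, seed = si + exp_id,
                       trials_per_cell = config$trials_per_cell,
                       duration_s = config$duration_s)
    })
    list(exp1 = if (1 %in% config$experiments) make(1, s1),
         exp2 = if (2 %in% config$experiments) make(2, s2),
         ptc1 = seq_len(config$n_subjects_exp1),
         ptc2 = c(seq_len(config$n_shared),
                  config$n_subjects_exp1 +
                    seq_len(config$n_subjects_exp2 - config$n_shared)))
  })
  if (is.null(cohorts$exp2) && !is.null(cohorts$exp1)) {
    stop2("bad_input", "A+V stage requires experiment cells; run both experiments")
  }

  inventory <- if (!done("decoders.csv")) stage("decode", {
    inv <- decoder_inventory(cohorts$exp1[[1]], cohorts$exp2[[1]], lags,
                             lambda_grid = grid)
    tab <- do.call(rbind, lapply(names(inv), function(nm) data.frame(
      decoder = nm, kind = inv[[nm]]$kind, lambda = inv[[nm]]$lambda,
      n_channels = inv[[nm]]$n_channels, n_lags = length(inv[[nm]]$lags$lags))))
    if (!is.null(out_dir)) write_result_csv(tab, outfile("decoders.csv"),
                                            hash, config$seed)
    inv
  }) else NULL

  msi_tab <- if (!done("msi.csv")) stage("msi", {
    rows <- list()
    for (side in c("exp1", "exp2")) {
      cohort <- cohorts[[side]]
      ptc <- cohorts[[if (side == "exp1") "ptc1" else "ptc2"]]
      gazes <- if (side == "exp1") "c" else c("d", "e")
      for (i in seq_along(cohort)) for (gz in gazes) {
        for (att in c("attended", "unattended")) {
          m <- subject_msi(cohort[[i]], att, gz, lags, grid)
          rows[[length(rows) + 1]] <- data.frame(
            ptc = ptc[i], exp = if (side == "exp1") 1 else 2, gaze = gz,
            attention = att, r_av = m$mean_r_av, r_sum = m$mean_r_sum,
            msi = m$msi)
        }
      }
    }
    tab <- do.call(rbind, rows)
    if (!is.null(out_dir)) write_result_csv(tab, outfile("msi.csv"),
                                            hash, config$seed)
    tab
  }) else utils::read.csv(outfile("msi.csv"), comment.char = "#")

  behavior <- if (!done("behavior.csv")) stage("behavior", {
    rows <- list()
    for (side in c("exp1", "exp2")) {
      cohort <- cohorts[[side]]
      ptc <- cohorts[[if (side == "exp1") "ptc1" else "ptc2"]]
      for (i in seq_along(cohort)) {
        sch <- cohort[[i]]$schedule
        ev <- simulate_behavior(sch, seed = cohort[[i]]$seed)
        dp <- dprime(ev, "glitch")
        qa <- merge(ev$comprehension,
                    data.frame(trial = sch$trial, gaze = sch$gaze))
        rows[[length(rows) + 1]] <- data.frame(
          ptc = ptc[i], exp = if (side == "exp1") 1 else 2,
          dprime_glitch = dp$dprime,
          comprehension = sum(qa$n_correct) / sum(qa$n_questions))
      }
    }
    tab <- do.call(rbind, rows)
    if (!is.null(out_dir)) write_result_csv(tab, outfile("behavior.csv"),
                                            hash, config$seed)
    tab
  }) else utils::read.csv(outfile("behavior.csv"), comment.char = "#")

  lme_tab <- stage("lme", {
    gz_code <- c(d = 0, c = 1, e = 2)
    d_att <- msi_tab[msi_tab$attention == "attended", ]
    d_att$gz <- gz_code[d_att$gaze]
    fits <- list()
    for (resp in c("r_av", "msi")) {
      d <- data.frame(value = d_att[[resp]], gz = d_att$gz, exp = d_att$exp,
                      ptc = d_att$ptc)
      full <- fit_lme(d, "value", c("gz", "exp"), "ptc")
      red <- fit_lme(d, "value", "exp", "ptc")
      fits[[resp]] <- list(fit = full, llr = llr_test(full, red))
    }
    tab <- do.call(rbind, lapply(names(fits), function(nm) data.frame(
      response = nm, beta_gz = unname(fits[[nm]]$fit$beta["gz"]),
      se = unname(fits[[nm]]$fit$se["gz"]),
      p_wald = unname(fits[[nm]]$fit$p["gz"]),
      llr = fits[[nm]]$llr$llr, p_llr = fits[[nm]]$llr$p)))
    if (!is.null(out_dir)) write_result_csv(tab, outfile("lme.csv"),
                                            hash, config$seed)
    fits
  })

  list(inventory = inventory, msi = msi_tab, behavior = behavior,
       lme = lme_tab, config_hash = hash)
}
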