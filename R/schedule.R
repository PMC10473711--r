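#' Build a trial schedule for one of the two attention experiments
#'
#' Experiment 1 presents two concurrent audiovisual speakers while the
#' participant fixates a central crosshair: 20 trials for each attended
#' modality (AV, A, V), 60 trials in total, all with gaze `"c"`.
#' Experiment 2 manipulates gaze (direct looking `"d"` vs eavesdropping
#' `"e"`): 14 trials per attended-modality-by-gaze cell, 84 trials in
#' total. The attended side is balanced within every cell (to within one
#' trial when the cell count is odd), and trial order is randomised.
#'
#' On AV trials the attended stream is congruent (audio dubbed to its
#' own video); on A and V trials it is incongruent, which decorrelates
#' the heard audio from the visible face so that unisensory decoders can
#' be fit. The unattended stream mirrors the attended stream's
#' congruence.
#'
#' @param experiment Integer, 1 or 2.
#' @param seed Integer RNG seed; the schedule is a pure function of
#'   `(experiment, seed)`.
#' @param trials_per_cell Optional override of the per-cell trial count
#'   (defaults: 20 for experiment 1, 14 for experiment 2). Used to run
#'   reduced simulated designs.
#' @param duration_s Trial duration in seconds (default 60).
#' @return A data.frame with columns `trial`, `modality` (`"AV"`, `"A"`,
#'   `"V"`), `gaze` (`"c"`, `"d"`, `"e"`), `attended_side` (`"L"`/`"R"`),
#'   `congruent_att`, `congruent_unatt` (logical) and `duration_s`, with
#'   attribute `experiment`.
#' @examples
#' sch <- make_schedule(1, seed = 1)
#' nrow(sch)            # 60
#' table(sch$modality)  # 20 each
#' @export
make_schedule <- function(experiment, seed = 1, trials_per_cell = NULL,
                          duration_s = 60) {
  if (!experiment %in% c(1, 2)) {
    stop2("bad_input", "unknown experiment id: %s", format(experiment))
  }
  cells <- if (experiment == 1) {
    expand.grid(modality = c("AV", "A", "V"), gaze = "c",
                stringsAsFactors = FALSE)
  } else {
    expand.grid(modality = c("AV", "A", "V"), gaze = c("d", "e"),
                stringsAsFactors = FALSE)
  }
  k <- if (is.null(trials_per_cell)) if (experiment == 1) 20L else 14L
       else as.integer(trials_per_cell)
  if (k < 1) stop2("bad_input", "trials_per_cell must be >= 1")

  with_seed(seed, {
    rows <- lapply(seq_len(nrow(cells)), function(i) {
      n_l <- k %/% 2
      side <- c(rep("L", n_l), rep("R", k - n_l))
      if (k %% 2 == 1 && stats::runif(1) < 0.5) side[k] <- "L"
      data.frame(modality = cells$modality[i], gaze = cells$gaze[i],
                 attended_side = sample(side),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[sample.int(nrow(out)), , drop = FALSE]
    out$congruent_att <- out$modality == "AV"
    out$congruent_unatt <- out$modality == "AV"
    out$duration_s <- duration_s
    out <- cbind(trial = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    attr(out, "experiment") <- experiment
    out
  })
}
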