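## Shared fixtures: small forward models and subjects, built in code.

## Reduced ridge grid for fast fits in unit tests.
small_grid <- function() 10^seq(-2, 6, 2)

## A compact forward model; near-delta auditory kernel on request makes
## the convolution exactly invertible within the decoding lag window.
tiny_fm <- function(n_channels = 8, noise_sd = 1, seed = 1, delta = FALSE,
                    ...) {
  kernels <- if (delta) {
    with_seed_local(seed, list(
      h_A = response_kernel(64, n_channels, c(0, 15), 10, "cosine"),
      h_V = response_kernel(64, n_channels, c(-200, 300), 0, "cosine"),
      h_I = response_kernel(64, n_channels, c(200, 400), 300, "gamma")))
  } else NULL
  forward_model(n_channels = n_channels, noise_sd = noise_sd, seed = seed,
                kernels = kernels, ...)
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

tiny_subject <- function(fm = tiny_fm(), seed = 1, trials_per_cell = 3,
                         duration_s = 15, ...) {
  simulate_subject(1, fm, seed = seed, trials_per_cell = trials_per_cell,
                   duration_s = duration_s, ...)
}

## Extract (eegs, envs) for a condition cell without exporting internals.
cell <- function(subject, kind, attention = "attended", gaze = "c") {
  sch <- subject$schedule
  idx <- which(sch$modality == kind & sch$gaze == gaze)
  field <- if (kind == "V") {
    if (attention == "attended") "env_face_att" else "env_face_unatt"
  } else {
    if (attention == "attended") "env_audio_att" else "env_audio_unatt"
  }
  list(eegs = lapply(subject$trials[idx], `[[`, "eeg"),
       envs = lapply(subject$trials[idx], `[[`, field))
}

## Simulate a gaze-effect dataset: per-participant random intercepts,
## numeric gaze code 0/1/2, optional experiment offset.
sim_gaze_data <- function(n_ptc = 20, slope = -0.5, sd_ptc = 0.3,
                          sd_eps = 0.4, exp_effect = 0.2, seed = 1) {
  with_seed_local(seed, {
    d <- expand.grid(ptc = seq_len(n_ptc), gz = 0:2)
    d$exp <- as.numeric(d$ptc > n_ptc / 2)
    u <- rnorm(n_ptc, sd = sd_ptc)
    d$value <- 1 + slope * d$gz + exp_effect * d$exp + u[d$ptc] +
      rnorm(nrow(d), sd = sd_eps)
    d
  })
}

## Random points on the upper unit hemisphere (synthetic electrode cap).
cap_positions <- function(n, seed = 1) {
  with_seed_local(seed, {
    az <- runif(n, 0, 2 * pi)
    el <- runif(n, pi / 8, pi / 2)
    cbind(cos(el) * cos(az), cos(el) * sin(az), sin(el))
  })
}
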