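test_that("band-pass transfer function meets its contract", {
  fs <- 512
  t <- seq(0, 8, by = 1 / fs)[-1]
  amp <- function(f) {
    y <- eeg_bandpass(matrix(sin(2 * pi * f * t), 1), fs)
    # steady-state amplitude away from the edges
    core <- seq(fs, length(t) - fs)
    max(abs(y[1, core]))
  }
  expect_gt(amp(1), 0.95)                        # passband
  expect_gt(amp(10), 0.95)
  expect_lt(20 * log10(amp(55)), -20)            # line-noise region
  expect_lt(20 * log10(amp(0.05)), -20)          # drift region
  # DC offset removed
  y <- eeg_bandpass(matrix(5, 1, 4 * fs), fs)
  expect_lt(max(abs(y)), 5e-3 * 5)
  expect_error(eeg_bandpass(matrix(0, 1, 100), fs = 50),
               class = "avmsi_bad_input")
})

test_that("band-pass filtering is zero-phase", {
  fs <- 256
  t <- seq(0, 6, by = 1 / fs)[-1]
  x <- sin(2 * pi * 5 * t)
  y <- eeg_bandpass(matrix(x, 1), fs)[1, ]
  core <- seq(fs, length(t) - fs)
  expect_gt(cor(x[core], y[core]), 0.9999)       # no phase shift
})

test_that("resampling preserves duration, tones, and is idempotent", {
  fs <- 512
  t <- seq(0, 60, by = 1 / fs)[-1]
  x <- matrix(sin(2 * pi * 10 * t), 1)
  y <- eeg_resample(x, fs, 64)
  expect_equal(ncol(y), 3840)
  core <- seq(64, 3840 - 64)
  # input samples start at t = 1/fs, so the output grid carries the same
  # constant offset
  ref <- sin(2 * pi * 10 * ((seq_len(3840) - 1) / 64 + 1 / fs))
  ratio <- max(abs(y[1, core])) / 1
  expect_gte(ratio, 0.98); expect_lte(ratio, 1.02)
  expect_gt(cor(y[1, core], ref[core]), 0.999)   # phase preserved
  expect_equal(eeg_resample(y, 64, 64), y, tolerance = 1e-12)
})

test_that("mastoid re-referencing is exact algebra", {
  set.seed(1)
  eeg <- matrix(rnorm(6 * 50), 6)
  out <- rereference_mastoids(eeg, mastoids = c(5, 6))
  ref <- colMeans(eeg[5:6, ])
  # round trip: adding the reference back reconstructs the input
  expect_equal(sweep(out[1:4, ], 2, ref, `+`), eeg[1:4, ], tolerance = 1e-12)
  # zero mastoids leave the data unchanged
  eeg0 <- eeg; eeg0[5:6, ] <- 0
  expect_equal(rereference_mastoids(eeg0, 5:6), eeg0)
  # mastoids equal to a scalp channel null it out
  eeg1 <- eeg; eeg1[5, ] <- eeg1[1, ]; eeg1[6, ] <- eeg1[1, ]
  expect_equal(rereference_mastoids(eeg1, 5:6)[1, ], rep(0, 50))
  expect_error(rereference_mastoids(eeg, 7:8), class = "avmsi_bad_input")
})

test_that("the variance rule flags a scaled-up channel", {
  set.seed(2)
  eeg <- matrix(rnorm(16 * 1000), 16)
  eeg[4, ] <- 10 * eeg[4, ]
  flags <- detect_bad_channels(eeg)
  expect_true(flags[4])
  expect_equal(sum(flags), 1)
  crit <- attr(flags, "criteria")
  expect_gt(crit$variance[4], 3 * mean(crit$variance))
})

test_that("clean i.i.d. channels are rarely flagged", {
  set.seed(3)
  fp <- vapply(1:200, function(i) {
    any(detect_bad_channels(matrix(rnorm(16 * 800), 16)))
  }, logical(1))
  expect_lt(mean(fp), 0.05)
})

test_that("a sparse-spike channel is flagged by the kurtosis rule", {
  set.seed(4)
  eeg <- matrix(rnorm(16 * 1000), 16)
  spikes <- rep(0, 1000)
  spikes[sample(1000, 12)] <- 6 * c(-1, 1)
  eeg[7, ] <- spikes
  flags <- detect_bad_channels(eeg)
  expect_true(flags[7])
  expect_error(detect_bad_channels(matrix(rnorm(2 * 100), 2)),
               class = "avmsi_bad_input")
})

test_that("spherical-spline interpolation reconstructs smooth fields", {
  pos <- cap_positions(32, seed = 5)
  # smooth scalp field: low-order polynomial in the 3D coordinates
  field <- function(p, w) w[1] * p[, 1] + w[2] * p[, 2] + w[3] * p[, 3] +
    w[4] * p[, 1] * p[, 2]
  set.seed(6)
  tpts <- 40
  W <- matrix(rnorm(4 * tpts), 4)
  truth <- sapply(seq_len(tpts), function(k) field(pos, W[, k]))
  rs <- vapply(1:8, function(ch) {
    bad <- rep(FALSE, 32); bad[ch] <- TRUE
    corrupted <- truth; corrupted[ch, ] <- 999
    est <- interpolate_bad(corrupted, pos, bad)
    cor(est[ch, ], truth[ch, ])
  }, numeric(1))
  expect_gt(min(rs), 0.95)
  # unflagged channels are untouched, bitwise
  bad <- rep(FALSE, 32); bad[2] <- TRUE
  out <- interpolate_bad(truth, pos, bad)
  expect_identical(out[-2, ], truth[-2, ])
  # no flags: identity
  expect_identical(interpolate_bad(truth, pos, rep(FALSE, 32)), truth)
  expect_error(interpolate_bad(truth[1:5, ], pos[1:5, ], c(TRUE, TRUE, FALSE,
                                                           FALSE, FALSE)),
               class = "avmsi_bad_input")
})

test_that("interpolation of a copied neighbour tracks the neighbour", {
  pos <- cap_positions(24, seed = 7)
  # put channel 2 right next to channel 1
  pos[2, ] <- pos[1, ] + c(0.02, 0, 0)
  pos <- pos / sqrt(rowSums(pos^2))
  set.seed(8)
  # smooth-ish data: random low-rank spatial structure
  base <- sapply(1:30, function(k) pos %*% rnorm(3))
  eeg <- base + 0.05 * matrix(rnorm(24 * 30), 24)
  truth_neighbour <- eeg[1, ]
  bad <- rep(FALSE, 24); bad[2] <- TRUE
  est <- interpolate_bad(eeg, pos, bad)
  expect_gt(cor(est[2, ], truth_neighbour), 0.8)
})

test_that("per-channel z-scoring meets its contracts", {
  set.seed(9)
  eeg <- matrix(rnorm(5 * 200, sd = 4), 5)
  z <- zscore_channels(eeg)
  expect_equal(apply(z, 1, sd), rep(1, 5), tolerance = 1e-9)
  expect_equal(rowMeans(z), rep(0, 5), tolerance = 1e-12)
  expect_equal(zscore_channels(z), z, tolerance = 1e-12)     # idempotent
  expect_equal(zscore_channels(3 * eeg), z, tolerance = 1e-12) # scale-free
  eeg[2, ] <- 7
  expect_error(zscore_channels(eeg), class = "avmsi_degenerate")
})

test_that("the conditioning pipeline runs end to end deterministically", {
  set.seed(10)
  fs <- 256
  n_scalp <- 12
  t <- seq(0, 20, by = 1 / fs)[-1]
  scalp <- t(sapply(seq_len(n_scalp), function(i) {
    sin(2 * pi * (2 + i / 4) * t) + rnorm(length(t), sd = 0.5)
  }))
  scalp[3, ] <- scalp[3, ] * 12                    # one noisy channel
  mast <- matrix(rnorm(2 * length(t), sd = 0.2), 2)
  eeg <- rbind(scalp, mast)
  pos <- cap_positions(n_scalp, seed = 11)
  out1 <- preprocess_eeg(eeg, fs, mastoids = n_scalp + 1:2, positions = pos)
  out2 <- preprocess_eeg(eeg, fs, mastoids = n_scalp + 1:2, positions = pos)
  expect_identical(out1$data, out2$data)
  expect_equal(out1$fs, 64)
  expect_equal(nrow(out1$data), n_scalp)
  expect_equal(ncol(out1$data), 20 * 64)
  expect_true(out1$bad[3])
  expect_equal(apply(out1$data, 1, sd), rep(1, n_scalp), tolerance = 1e-9)
})
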