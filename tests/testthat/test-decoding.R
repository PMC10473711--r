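test_that("lag grids match the published design constants", {
  g <- lag_grid(0, 500, 64)
  expect_length(g$lags, 33)
  s <- lag_grid(-500, 500, 64)
  expect_length(s$lags, 65)
  expect_equal(unique(round(diff(s$lags_ms), 6)), 15.625)
  expect_equal(length(default_lambda_grid()), 19)
  expect_equal(range(default_lambda_grid()), c(1e-6, 1e30))
})

test_that("lagged design follows the shift/pad rule", {
  # hand enumeration: single channel (a, b, c), lags {0, 1}
  X <- build_lagged_design(matrix(c(1, 2, 3), 1), c(0L, 1L), intercept = FALSE)
  expect_equal(X, rbind(c(1, 2), c(2, 3), c(3, 0)))
  # lag {0} reproduces the EEG transposed
  eeg <- matrix(rnorm(4 * 20), 4)
  expect_equal(build_lagged_design(eeg, 0L, intercept = FALSE), t(eeg))
  # negative lags shift the other way
  Xn <- build_lagged_design(matrix(c(1, 2, 3), 1), c(-1L, 0L), intercept = FALSE)
  expect_equal(Xn, rbind(c(0, 1), c(1, 2), c(2, 3)))
  expect_error(build_lagged_design(eeg, 40L), class = "avmsi_bad_input")
})

test_that("solve_ridge matches an explicit normal-equations oracle", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(20:60, 1); p <- sample(3:8, 1)
    X <- cbind(matrix(rnorm(n * p), n), 1)
    y <- rnorm(n)
    lam <- 10^runif(1, -3, 3)
    acc <- structure(list(XtX = crossprod(X), Xty = drop(crossprod(X, y)),
                          intercept = TRUE, n_trials = 1),
                     class = "cov_acc")
    g <- solve_ridge(acc, lam)
    pen <- diag(c(rep(lam, p), 0))
    oracle <- solve(crossprod(X) + pen, crossprod(X, y))
    expect_lt(max(abs(g - oracle)), 1e-10)
  }
})

test_that("ridge limits behave analytically", {
  set.seed(2)
  X <- matrix(rnorm(40 * 5), 40)
  y <- rnorm(40)
  acc <- structure(list(XtX = crossprod(X), Xty = drop(crossprod(X, y)),
                        intercept = FALSE, n_trials = 1), class = "cov_acc")
  # heavy shrinkage: g -> Xty / lambda
  g_big <- solve_ridge(acc, 1e12)
  expect_lt(sqrt(sum(g_big^2)), 1e-9 * sqrt(sum(acc$Xty^2)))
  # orthonormal columns at lambda = 0: g = Xty exactly
  Q <- qr.Q(qr(matrix(rnorm(50 * 6), 50)))
  acc_q <- structure(list(XtX = crossprod(Q), Xty = drop(crossprod(Q, y[1:50])),
                          intercept = FALSE, n_trials = 1), class = "cov_acc")
  expect_equal(solve_ridge(acc_q, 0), acc_q$Xty, tolerance = 1e-10)
  # singular system at lambda = 0 is signalled
  Xs <- cbind(1:10, 1:10)
  acc_s <- structure(list(XtX = crossprod(Xs), Xty = drop(crossprod(Xs, rnorm(10))),
                          intercept = FALSE, n_trials = 1), class = "cov_acc")
  expect_error(solve_ridge(acc_s, 0), class = "avmsi_singular")
})

test_that("shrinkage is monotone in lambda", {
  sub <- tiny_subject(tiny_fm(seed = 3), seed = 3, trials_per_cell = 2,
                      duration_s = 8)
  cl <- cell(sub, "AV")
  acc <- cov_accumulate(cl$eegs, cl$envs, lag_grid(0, 200))
  norms <- vapply(10^seq(-4, 8, 2), function(l) {
    g <- solve_ridge(acc, l)
    sqrt(sum(g[-length(g)]^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("covariance accumulation is additive and order-invariant", {
  sub <- tiny_subject(tiny_fm(seed = 5), seed = 5, trials_per_cell = 3,
                      duration_s = 6)
  cl <- cell(sub, "AV")
  lg <- lag_grid(0, 150)
  a12 <- cov_accumulate(cl$eegs, cl$envs, lg)
  a21 <- cov_accumulate(rev(cl$eegs), rev(cl$envs), lg)
  expect_equal(a12$XtX, a21$XtX, tolerance = 1e-12)
  expect_equal(a12$Xty, a21$Xty, tolerance = 1e-12)
  split_sum <- cov_accumulate(cl$eegs[1], cl$envs[1], lg) +
    cov_accumulate(cl$eegs[2:3], cl$envs[2:3], lg)
  expect_equal(split_sum$XtX, a12$XtX, tolerance = 1e-12)
})

test_that("in-sample fit on a full-rank design is exact", {
  set.seed(8)
  eeg <- matrix(rnorm(8 * 100), 8)    # 8 ch x 17 lags + 1 = 137 cols > 100 rows
  env <- rnorm(100)
  dec <- envelope_decoder(eeg, env, lag_grid(0, 250), lambda = 1e-8)
  r <- reconstruct(dec, eeg, env)
  expect_gte(r$scores$r, 0.999)
})

test_that("degenerate reconstructions are signalled, not scored zero", {
  sub <- tiny_subject(tiny_fm(seed = 6), seed = 6, trials_per_cell = 2,
                      duration_s = 6)
  cl <- cell(sub, "AV")
  dec <- envelope_decoder(cl$eegs, cl$envs, lag_grid(0, 100), lambda = 1)
  dec$weights[] <- 0
  expect_error(reconstruct(dec, cl$eegs, cl$envs),
               class = "avmsi_degenerate")
  # constant target
  dec2 <- envelope_decoder(cl$eegs, cl$envs, lag_grid(0, 100), lambda = 1)
  expect_error(reconstruct(dec2, cl$eegs[1], list(rep(1, 384))),
               class = "avmsi_degenerate")
})

test_that("reconstruction r is invariant to affine rescaling of the target", {
  sub <- tiny_subject(tiny_fm(seed = 9), seed = 9, trials_per_cell = 2,
                      duration_s = 6)
  cl <- cell(sub, "AV")
  dec <- envelope_decoder(cl$eegs, cl$envs, lag_grid(0, 100), lambda = 10)
  r1 <- reconstruct(dec, cl$eegs, cl$envs)$scores$r
  r2 <- reconstruct(dec, cl$eegs, lapply(cl$envs, function(e) 3 * e + 7))$scores$r
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("cross-validated lambda equals the exhaustive-search maximiser", {
  sub <- tiny_subject(tiny_fm(seed = 12, noise_sd = 2), seed = 12,
                      trials_per_cell = 4, duration_s = 8)
  cl <- cell(sub, "AV")
  lg <- lag_grid(0, 150)
  grid <- small_grid()
  sel <- crossval_lambda(cl$eegs, cl$envs, lg, grid)
  # independent brute-force loop refitting each fold from scratch
  brute <- vapply(grid, function(lam) {
    rs <- vapply(seq_along(cl$eegs), function(i) {
      tr_e <- cl$eegs[-i]; tr_s <- cl$envs[-i]
      Xs <- lapply(tr_e, build_lagged_design, lags = lg)
      XtX <- Reduce(`+`, lapply(Xs, crossprod))
      Xty <- Reduce(`+`, Map(function(X, s) drop(crossprod(X, s)), Xs, tr_s))
      pen <- diag(c(rep(lam, ncol(XtX) - 1), 0))
      g <- solve(XtX + pen, Xty)
      cor(drop(build_lagged_design(cl$eegs[[i]], lg) %*% g), cl$envs[[i]])
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_equal(sel$cv$mean_r, brute, tolerance = 1e-8)
  expect_equal(sel$lambda, grid[which.max(brute)])
  # single-candidate grid returns that candidate
  one <- envelope_decoder(cl$eegs, cl$envs, lg, lambda_grid = 100)
  expect_equal(one$lambda, 100)
})

test_that("cross-validation ties break toward the larger lambda", {
  sub <- tiny_subject(tiny_fm(seed = 1), seed = 1, trials_per_cell = 2,
                      duration_s = 6)
  cl <- cell(sub, "AV")
  # duplicated candidate values force an exact tie
  sel <- crossval_lambda(cl$eegs, cl$envs, lag_grid(0, 100), c(10, 10, 10))
  expect_equal(sel$lambda, 10)
})

test_that("summed covariances equal the doubled concatenation algebraically", {
  sub <- tiny_subject(tiny_fm(seed = 14), seed = 14, trials_per_cell = 2,
                      duration_s = 8)
  a <- cell(sub, "A"); av <- cell(sub, "AV")
  lg <- lag_grid(0, 150)
  lam <- 100
  # trials_A = trials_V (identical data and targets)
  dec_sum <- fit_sum_decoder(a$eegs, a$envs, a$eegs, a$envs,
                             av$eegs, av$envs, lg, lambda = lam)
  dec_dbl <- envelope_decoder(c(a$eegs, a$eegs), c(a$envs, a$envs), lg,
                              lambda = lam)
  expect_lt(max(abs(dec_sum$weights - dec_dbl$weights)), 1e-12)
})

test_that("sum decoder matches a hand-summed normal-equations oracle", {
  sub <- tiny_subject(tiny_fm(seed = 15), seed = 15, trials_per_cell = 1,
                      duration_s = 6)
  a <- cell(sub, "A"); v <- cell(sub, "V"); av <- cell(sub, "AV")
  lg <- lag_grid(0, 100)
  lam <- 10
  dec <- fit_sum_decoder(a$eegs, a$envs, v$eegs, v$envs, av$eegs, av$envs,
                         lg, lambda = lam)
  Xa <- build_lagged_design(a$eegs[[1]], lg)
  Xv <- build_lagged_design(v$eegs[[1]], lg)
  XtX <- crossprod(Xa) + crossprod(Xv)
  Xty <- drop(crossprod(Xa, a$envs[[1]])) + drop(crossprod(Xv, v$envs[[1]]))
  pen <- diag(c(rep(lam, ncol(XtX) - 1), 0))
  expect_lt(max(abs(dec$weights - solve(XtX + pen, Xty))), 1e-9)
  expect_error(fit_sum_decoder(list(), list(), v$eegs, v$envs,
                               av$eegs, av$envs, lg),
               class = "avmsi_bad_input")
})

test_that("sum-decoder lambda is optimised against the AV trials", {
  sub <- tiny_subject(tiny_fm(seed = 16, noise_sd = 2), seed = 16,
                      trials_per_cell = 3, duration_s = 8)
  a <- cell(sub, "A"); v <- cell(sub, "V"); av <- cell(sub, "AV")
  lg <- lag_grid(0, 150)
  grid <- small_grid()
  dec <- fit_sum_decoder(a$eegs, a$envs, v$eegs, v$envs, av$eegs, av$envs,
                         lg, lambda_grid = grid)
  # the stored curve is the AV-trial evaluation; winner maximises it
  expect_equal(dec$lambda,
               max(grid[dec$cv$mean_r >= max(dec$cv$mean_r) - 1e-15]))
  r_win <- reconstruct(dec, av$eegs, av$envs)$mean_r
  expect_equal(r_win, max(dec$cv$mean_r), tolerance = 1e-10)
})

test_that("noiseless pipeline round trip reconstructs near-perfectly", {
  fm <- tiny_fm(n_channels = 6, noise_sd = 0, seed = 21, delta = TRUE,
                gain_unatt = 0,
                gain_visual_by_gaze = c(direct = 0, crosshair = 0,
                                        eavesdrop = 0))
  sub <- simulate_subject(1, fm, seed = 21, trials_per_cell = 3,
                          duration_s = 10)
  cl <- cell(sub, "AV")
  dec <- envelope_decoder(cl$eegs, cl$envs, lag_grid(0, 250),
                          lambda_grid = 10^seq(-6, 2, 2))
  expect_gt(max(dec$cv$mean_r), 0.99)
})

test_that("condition decoders cover the 24-decoder inventory", {
  fm1 <- tiny_fm(n_channels = 6, seed = 31)
  s1 <- simulate_subject(1, fm1, seed = 31, trials_per_cell = 2,
                         duration_s = 8)
  s2 <- simulate_subject(2, tiny_fm(n_channels = 6, seed = 32), seed = 32,
                         trials_per_cell = 2, duration_s = 8)
  inv <- decoder_inventory(s1, s2, lag_grid(0, 150), lambda = 10)
  expect_length(inv, 24)
  expect_setequal(unique(vapply(inv, `[[`, "", "kind")),
                  c("AV", "A", "V", "A+V"))
  gz <- vapply(strsplit(names(inv), "_"), `[[`, "", 2)
  expect_equal(unname(table(gz)), rep(8L, 3), ignore_attr = TRUE)
  # empty condition cells are rejected
  expect_error(fit_condition_decoder(s1, "AV", gaze = "d"),
               class = "avmsi_bad_input")
})

test_that("attended and unattended decoders coincide for identical streams", {
  sub <- tiny_subject(tiny_fm(seed = 33), seed = 33, trials_per_cell = 2,
                      duration_s = 8)
  # make the two streams identical on the AV trials
  idx <- which(sub$schedule$modality == "AV")
  for (i in idx) {
    sub$trials[[i]]$env_audio_unatt <- sub$trials[[i]]$env_audio_att
  }
  d_att <- fit_condition_decoder(sub, "AV", "attended", "c",
                                 lag_grid(0, 100), lambda = 10)
  d_un <- fit_condition_decoder(sub, "AV", "unattended", "c",
                                lag_grid(0, 100), lambda = 10)
  expect_equal(d_att$weights, d_un$weights, tolerance = 1e-12)
})
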