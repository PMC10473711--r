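test_that("signed-rank matches brute-force enumeration of sign patterns", {
  set.seed(1)
  a <- round(rnorm(8), 3)
  b <- round(rnorm(8), 3)
  d <- a - b
  got <- signed_rank(a, b)
  # exact null: V over all 2^8 sign assignments of the ranked |d|
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 8)))
  v_null <- signs %*% rk
  p_exact <- mean(v_null <= min(v_obs, sum(rk) - v_obs)) * 2
  p_exact <- min(p_exact, 1)
  expect_true(got$exact)
  expect_equal(got$statistic, v_obs)
  expect_equal(got$p, p_exact, tolerance = 1e-12)
})

test_that("signed-rank contracts: zeros, identity, symmetry", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(signed_rank(x, x)$p, 1)
  expect_equal(signed_rank(x, x)$n, 0)
  y <- x + c(0.5, -0.2, 0.3, -0.1, 0.4)
  expect_equal(signed_rank(x, y)$p, signed_rank(y, x)$p)
  # zeros are dropped per convention
  expect_equal(signed_rank(c(0, 0, 1, 2, 3), 0)$n, 3)
})

test_that("rank-sum matches exhaustive enumeration of labellings", {
  a <- c(1.3, 2.7, 0.5)
  b <- c(3.1, 4.2, 2.9)
  got <- rank_sum(a, b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  w_obs <- sum(rk[1:3]) - 3 * 4 / 2
  combs <- combn(6, 3)
  w_null <- apply(combs, 2, function(idx) sum(rk[idx]) - 6)
  p_exact <- mean(abs(w_null - 4.5) >= abs(w_obs - 4.5))
  expect_true(got$exact)
  expect_equal(got$statistic, w_obs)
  expect_equal(got$p, p_exact, tolerance = 1e-12)
  # label-swap invariance and the identical-group contract
  expect_equal(rank_sum(a, b)$p, rank_sum(b, a)$p)
  expect_equal(rank_sum(c(2, 2, 2), c(2, 2, 2))$p, 1)
  expect_error(rank_sum(numeric(0), b), class = "avmsi_bad_input")
})

test_that("Benjamini-Hochberg matches a hand-run of the step-up rule", {
  # all small p at m = 10: everything rejected
  out <- fdr_bh(rep(0.01, 10), q = 0.05)
  expect_true(all(out$reject))
  # hand-run case: sorted p = (.005, .01, .03, .04) vs k q / m =
  # (.0125, .025, .0375, .05): every p_(k) <= k q / m, so all rejected
  p <- c(0.01, 0.04, 0.03, 0.005)
  out2 <- fdr_bh(p, q = 0.05)
  expect_equal(out2$reject, rep(TRUE, 4))
  expect_equal(out2$p_adj, p.adjust(p, "BH"))
  # partial case: sorted (.001, .02, .04, .9); .04 > 3 * .0125 and the
  # step-up stops at k = 2
  out3 <- fdr_bh(c(0.001, 0.02, 0.04, 0.9), q = 0.05)
  expect_equal(out3$reject, c(TRUE, TRUE, FALSE, FALSE))
  # single p: reject iff p <= q
  expect_true(fdr_bh(0.05, 0.05)$reject)
  expect_false(fdr_bh(0.051, 0.05)$reject)
  expect_length(fdr_bh(numeric(0))$reject, 0)
  # rejections grow as q grows
  p3 <- c(0.001, 0.01, 0.02, 0.2, 0.6)
  r1 <- fdr_bh(p3, 0.02)$reject
  r2 <- fdr_bh(p3, 0.1)$reject
  expect_true(all(r2[r1]))
})

test_that("d-prime matches the inverse-normal oracle", {
  # construct events with known hit/fa structure: 10 targets, 9 hits,
  # and false alarms filling 10% of the non-target windows
  targets <- data.frame(trial = 1, time = seq(0, 54, by = 6)[1:10],
                        kind = "glitch")
  hits <- data.frame(trial = 1, time = targets$time[1:9] + 0.5)
  # non-target windows: (60 - 10*2)/2 = 20; 2 false alarms
  fas <- data.frame(trial = 1, time = c(3.1, 9.3))
  ev <- list(targets = targets, responses = rbind(hits, fas), duration_s = 60)
  dp <- dprime(ev, "glitch")
  expect_equal(dp$hits, 9)
  expect_equal(dp$false_alarms, 2)
  expect_equal(dp$n_nontarget_windows, 20)
  expect_equal(dp$dprime, qnorm(0.9) - qnorm(0.1), tolerance = 1e-12)
  expect_equal(qnorm(0.9) - qnorm(0.1), 2.563, tolerance = 1e-3)
})

test_that("d-prime handles edge rates and monotonicity", {
  mk <- function(n_hit, n_fa) {
    targets <- data.frame(trial = 1, time = seq(0, 54, by = 6)[1:10],
                          kind = "glitch")
    resp <- rbind(
      if (n_hit > 0) data.frame(trial = 1, time = targets$time[seq_len(n_hit)] + 1)
      else NULL,
      if (n_fa > 0) data.frame(trial = 1, time = 2.5 + 0.01 * seq_len(n_fa))
      else NULL)
    list(targets = targets,
         responses = if (is.null(resp)) data.frame(trial = integer(),
                                                   time = numeric()) else resp,
         duration_s = 60)
  }
  # perfect rates are clamped, not infinite
  expect_true(is.finite(dprime(mk(10, 0), "glitch")$dprime))
  # d' increases in hits, decreases in false alarms
  expect_gt(dprime(mk(9, 1), "glitch")$dprime, dprime(mk(7, 1), "glitch")$dprime)
  expect_gt(dprime(mk(8, 1), "glitch")$dprime, dprime(mk(8, 3), "glitch")$dprime)
  # equal rates give 0
  ev0 <- mk(2, 4)   # 2/10 hits, 4/20 fa
  expect_equal(dprime(ev0, "glitch")$dprime, 0, tolerance = 1e-12)
  expect_error(dprime(mk(0, 0), "slowmotion"), class = "avmsi_degenerate")
})

test_that("slow-motion events use the 4 s window", {
  targets <- data.frame(trial = 1, time = c(0, 10, 20), kind = "slowmotion")
  resp <- data.frame(trial = 1, time = c(3.5, 14.5, 21))
  ev <- list(targets = targets, responses = resp, duration_s = 60)
  dp <- dprime(ev, "slowmotion")
  expect_equal(dp$hits, 2)           # 3.5 in [0,4]; 14.5 outside [10,14]; 21 in
  expect_equal(dp$false_alarms, 1)
  expect_equal(dp$n_nontarget_windows, floor((60 - 3 * 4) / 4))
})

test_that("comprehension scores are tested one-sided against chance", {
  expect_equal(comprehension_test(rep(0.25, 10))$p, 1)
  hi <- comprehension_test(c(0.7, 0.65, 0.8, 0.75, 0.6, 0.7))
  expect_lt(hi$p, 0.05)
  # all-correct cohort attains the minimal one-sided exact p for n
  n <- 8
  all_right <- comprehension_test(rep(1, n) - seq(0, 1e-6, length.out = n))
  expect_equal(all_right$p, 2^-n, tolerance = 1e-9)
})

test_that("the permutation machinery reproduces the identity assignment", {
  fm <- tiny_fm(n_channels = 4, noise_sd = 2, seed = 40)
  sub <- simulate_subject(1, fm, seed = 40, trials_per_cell = 4,
                          duration_s = 8)
  cl <- cell(sub, "AV")
  lg <- lag_grid(0, 150)
  grid <- c(10, 1000)
  nl <- suppressWarnings(permutation_null(cl$eegs, cl$envs, lg, n_perm = 30,
                                          seed = 2, lambda_grid = grid))
  # the actual value equals an independent run of the standard CV path
  sel <- crossval_lambda(cl$eegs, cl$envs, lg, grid)
  expect_equal(nl$actual_r, max(sel$cv$mean_r), tolerance = 1e-10)
  expect_length(nl$null_r, 30)
  # shuffled pairings decode worse than the true pairing
  expect_gt(nl$actual_r, nl$null_mean)
  expect_error(permutation_null(cl$eegs[1:2], cl$envs[1:2], lg),
               class = "avmsi_bad_input")
})

test_that("permutation nulls are exchangeable under the generative null", {
  # envelope-independent EEG: the actual r should rank uniformly within
  # its own null distribution
  set.seed(41)
  lg <- lag_grid(0, 150)
  ranks <- vapply(1:24, function(i) {
    eegs <- replicate(5, matrix(rnorm(3 * 320), 3), simplify = FALSE)
    envs <- replicate(5, rnorm(320), simplify = FALSE)
    nl <- suppressWarnings(permutation_null(eegs, envs, lg, n_perm = 19,
                                            seed = i, lambda_grid = 100))
    mean(nl$null_r < nl$actual_r)
  }, numeric(1))
  # ranks spread over [0,1] rather than piling at the extremes
  expect_gt(mean(ranks > 0.1 & ranks < 0.9), 0.5)
  expect_gt(mean(ranks), 0.25); expect_lt(mean(ranks), 0.75)
})
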