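test_that("exponential fit recovers exact parameters and applies exclusion rules", {
  x <- 1:100
  y <- 10 * exp(-x / 15.7) + 2
  fit <- fit_learning_curve(y, x)
  expect_equal(fit$b, 15.7, tolerance = 1e-6)
  expect_equal(fit$a, 10, tolerance = 1e-5)
  expect_equal(fit$c, 2, tolerance = 1e-6)
  expect_true(is.na(fit$excluded_reason))

  # monotone linear series: infinite learning rate, excluded
  lin <- fit_learning_curve(0.5 * x + 3, x)
  expect_identical(lin$excluded_reason, "linear_fit")

  # increasing exponential towards a plateau fits with negative a, b > 0
  y2 <- -8 * exp(-x / 12) + 5
  fit2 <- fit_learning_curve(y2, x)
  expect_equal(fit2$b, 12, tolerance = 1e-5)
  expect_lt(fit2$a, 0)

  # growing exponential: negative time constant, excluded
  y3 <- 2 * exp(x / 40)
  fit3 <- fit_learning_curve(y3, x)
  expect_identical(fit3$excluded_reason, "negative_b")
})

test_that("noisy fits recover the time constant within 10 % on average", {
  set.seed(11)
  bs <- replicate(40, {
    x <- 1:100
    y <- 10 * exp(-x / 15.7) + 2 + rnorm(100, sd = 0.1)
    fit_learning_curve(y, x)$b
  })
  expect_lt(abs(mean(bs) - 15.7) / 15.7, 0.10)
  expect_gt(mean(abs(bs - 15.7) / 15.7 < 0.10), 0.8)
})

test_that("plateau is b * log(20) exactly", {
  fit <- fit_learning_curve(10 * exp(-(1:100) / 15.7) + 2)
  expect_equal(plateau_trial(fit), fit$b * log(20))
  f1 <- fit
  f1$b <- 1; f1$a <- 5
  expect_equal(plateau_trial(f1), log(20), tolerance = 1e-12)
  expect_equal(round(15.7 * log(20), 2), 47.03)
  f0 <- fit; f0$a <- 0
  expect_equal(plateau_trial(f0), 0)
  bad <- fit; bad$excluded_reason <- "negative_b"
  expect_error(plateau_trial(bad), "not valid")
})

test_that("outcome contrasts match the hand-enumerated sequence", {
  df <- data.frame(
    block = "perturbed",
    outcome = c("success", "success", "failure_backward", "success",
                "success"),
    m = c(1, 1, NA, 2, 1))
  run <- structure(list(trials_df = df), class = "run_result")
  ct <- outcome_contrasts(list(run, run), metric_name = "m")
  expect_equal(ct$mean_delta_SS, -1)   # (1-1) + (1-2)
  expect_equal(ct$mean_delta_SFS, 1)   # 2-1 across the failure
  # constant series gives zero deltas
  df0 <- df; df0$m <- c(2, 2, NA, 2, 2)
  run0 <- structure(list(trials_df = df0), class = "run_result")
  ct0 <- outcome_contrasts(run0, "m")
  expect_equal(ct0$sum_ss, 0)
  expect_equal(ct0$sum_sfs, 0)
  # forward-step failures are excluded from pair construction:
  # S S(fwd-fail) S collapses to consecutive successes
  df1 <- data.frame(block = "perturbed",
                    outcome = c("success", "failure_forward", "success"),
                    m = c(1, NA, 3))
  run1 <- structure(list(trials_df = df1), class = "run_result")
  ct1 <- outcome_contrasts(run1, "m")
  expect_equal(ct1$sum_ss, 2)
  expect_equal(ct1$sum_sfs, 0)
  # no qualifying pairs: empty marker
  df2 <- data.frame(block = "perturbed", outcome = "success", m = 1)
  run2 <- structure(list(trials_df = df2), class = "run_result")
  expect_true(outcome_contrasts(run2, "m")$empty)
})

test_that("shuffled outcomes yield no systematic S-S versus S-F-S difference", {
  set.seed(21)
  diffs <- replicate(200, {
    df <- data.frame(block = "perturbed",
                     outcome = sample(c("success", "failure_backward"), 60,
                                      replace = TRUE, prob = c(0.7, 0.3)),
                     m = rnorm(60))
    run <- structure(list(trials_df = df), class = "run_result")
    ct <- outcome_contrasts(run, "m")
    if (isTRUE(ct$empty)) NA else ct$mean_delta_SFS - ct$mean_delta_SS
  })
  expect_lt(abs(mean(diffs, na.rm = TRUE)), 0.25)
})

test_that("relative reduction reproduces its forced cases", {
  expect_equal(relative_reduction(1, 10, 1), 1)
  expect_equal(relative_reduction(10, 10, 1), 0)
  expect_equal(relative_reduction(4, 10, 1), 1 - 3 / 9)
  expect_error(relative_reduction(1, 5, 5), "undefined")
})

test_that("paired t matches a hand computation and flags degeneracies", {
  x <- c(3, 1, 5, 2, 4)
  y <- c(1, 2, 2, 2, 3)
  d <- x - y  # 2, -1, 3, 0, 1
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  res <- paired_t(x, y)
  expect_equal(res$t, t_hand, tolerance = 1e-9)
  expect_equal(res$p, 2 * stats::pt(-abs(t_hand), df = 4), tolerance = 1e-9)
  expect_equal(paired_t(c(1, 2, 3), c(1, 3, 2))$t, 0)
  expect_error(paired_t(c(2, 3, 4), c(1, 2, 3)), "zero variance")
})

test_that("correlation table is exact on self-pairs and calibrated on noise", {
  set.seed(5)
  a <- matrix(rnorm(3 * 84), 3)
  ct <- run_reference_correlations(a, a)
  self <- ct$pairs[ct$pairs$sim == ct$pairs$ref, ]
  expect_true(all(abs(self$r - 1) < 1e-12))
  expect_true(all(ct$pairs$r >= -1 & ct$pairs$r <= 1))
  # symmetric under swapping roles
  ct2 <- run_reference_correlations(a[1, , drop = FALSE],
                                    a[2, , drop = FALSE])
  ct3 <- run_reference_correlations(a[2, , drop = FALSE],
                                    a[1, , drop = FALSE])
  expect_equal(ct2$pairs$r, ct3$pairs$r)
  # independent white noise: about 5 % of pairs significant
  sim <- matrix(rnorm(25 * 84), 25)
  ref <- matrix(rnorm(40 * 84), 40)
  ctn <- run_reference_correlations(sim, ref)
  fp <- mean(ctn$pairs$p < 0.05)
  expect_gt(fp, 0.02)
  expect_lt(fp, 0.09)
  # constant series reported as undefined, not an error
  ctc <- run_reference_correlations(matrix(1, 1, 84), a[1, , drop = FALSE])
  expect_true(is.na(ctc$pairs$r[1]))
})

test_that("p-value adjustment dispatches to the requested method", {
  p <- c(0.01, 0.02, 0.04)
  expect_equal(adjust_pvalues(p, "bonferroni"), stats::p.adjust(p, "bonferroni"))
  expect_equal(adjust_pvalues(p, "BH"), stats::p.adjust(p, "BH"))
})
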