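test_that("canonical HRF has the expected double-gamma shape", {
  h <- canonical_hrf(2)
  expect_equal(h[1], 0)             # zero at onset
  expect_equal(max(h), 1)           # peak-normalised
  # peak between 4 and 7 seconds on a fine grid
  h_fine <- canonical_hrf(0.1)
  t_fine <- seq(0, 32, by = 0.1)
  expect_gte(t_fine[which.max(h_fine)], 4)
  expect_lte(t_fine[which.max(h_fine)], 7)
  # late undershoot: non-positive after 20 s
  expect_true(all(h_fine[t_fine > 20] <= 0))
})

test_that("beta-series design has one regressor per trial plus nuisance", {
  p <- acquisition_params()
  sch <- build_schedule("regulation", p, 1)
  des <- build_beta_series_design(sch, p)
  expect_equal(ncol(des$matrix), 24 + 2)
  expect_equal(des$trial_columns, 1:24)
  expect_equal(des$labels, sch$blocks$condition)
  # temporally distant trials are near-orthogonal
  cc <- cor(des$matrix[, 1], des$matrix[, 10])
  expect_lt(abs(cc), 0.2)
  # regressors are silent before the first onset
  trial_part <- des$matrix[, 1:24]
  first_onset_vol <- (20 + 10) / 2
  zero_rows <- which(rowSums(abs(trial_part)) == 0)
  expect_true(all(zero_rows <= first_onset_vol + 1))
  # motion columns are appended when supplied
  des_m <- build_beta_series_design(sch, p, motion = matrix(rnorm(sch$n_volumes * 6),
                                                           ncol = 6))
  expect_equal(ncol(des_m$matrix), 24 + 2 + 6)
})

test_that("trial betas are exact on noiseless data and match a pseudo-inverse", {
  p <- acquisition_params(n_voxels = 5L)
  sch <- build_schedule("regulation", p, 1)
  des <- build_beta_series_design(sch, p)
  set.seed(8)
  true_b <- matrix(rnorm(26 * 5), 26, 5)
  ydata <- des$matrix %*% true_b
  bs <- estimate_trial_betas(ydata, des)
  expect_equal(bs$betas, true_b[1:24, ], tolerance = 1e-8, ignore_attr = TRUE)

  # noisy case: equals the pseudo-inverse oracle
  ydata2 <- ydata + matrix(rnorm(length(ydata)), nrow(ydata))
  bs2 <- estimate_trial_betas(ydata2, des)
  ref <- pracma::pinv(des$matrix) %*% ydata2
  expect_equal(bs2$betas, ref[1:24, ], tolerance = 1e-8, ignore_attr = TRUE)

  # adding a constant to all volumes moves only the intercept
  bs3 <- estimate_trial_betas(ydata2 + 7, des)
  expect_equal(bs3$betas, bs2$betas, tolerance = 1e-8)
})

test_that("two-fold CV is perfect on separable patterns and matches a manual loop", {
  set.seed(10)
  labels24 <- rep(c("interoceptive", "exteroceptive"), 12)
  betas <- matrix(rnorm(24 * 6, sd = 0.1), 24, 6)
  betas[labels24 == "interoceptive", 1] <- betas[labels24 == "interoceptive", 1] + 5
  expect_equal(two_fold_cv_accuracy(betas, labels24), 1.0)

  # 8-trial toy: hand-rolled fold loop
  lab8 <- rep(c("interoceptive", "exteroceptive"), 4)
  x8 <- matrix(rnorm(8 * 3), 8, 3)
  x8[lab8 == "interoceptive", 2] <- x8[lab8 == "interoceptive", 2] + 1.5
  got <- two_fold_cv_accuracy(x8, lab8)
  y8 <- ifelse(lab8 == "interoceptive", 1, -1)
  fold <- integer(8)
  for (cls in c(1, -1)) fold[which(y8 == cls)] <- rep(1:2, 2)
  accs <- sapply(1:2, function(te) {
    tr <- fold != te
    fit <- train_linear_svm(x8[tr, ], y8[tr])
    pr <- sign(x8[!tr, ] %*% fit$weights + fit$bias)
    pr[pr == 0] <- -1
    mean(pr == y8[!tr])
  })
  expect_equal(got, mean(accs))
})

test_that("two-fold CV rejects unbalanced or single-class labels", {
  x <- matrix(rnorm(24 * 3), 24, 3)
  expect_error(two_fold_cv_accuracy(x, rep("interoceptive", 24)), "both classes")
  expect_error(two_fold_cv_accuracy(x, rep(c("interoceptive", "exteroceptive"),
                                           c(16, 8))), "balanced")
})

test_that("offline and online accuracy both beat chance on high-SNR data", {
  p <- acquisition_params(n_voxels = 20L)
  sch0 <- build_schedule("decoder_training", p, 0)
  sp <- subject_params("hi-snr", "NF", learnability = 0,
                      pattern_intero = rep(c(2, 0), 10),
                      pattern_extero = rep(c(0, 2), 10),
                      noise_sd = 1, drift_amplitude = 0.5)
  ts <- simulate_run(sch0, sp, 0, seed = 5, params = p)
  psc <- percent_signal_change(ts)
  # online path
  tf <- extract_trial_features(psc, sch0, p)
  m <- train_run_decoder(list(tf), 1)
  online_acc <- mean(sign(decision_value(m, tf)) ==
                       ifelse(tf$labels == "interoceptive", 1, -1))
  # offline path
  des <- build_beta_series_design(sch0, p)
  bs <- estimate_trial_betas(psc, des)
  offline_acc <- two_fold_cv_accuracy(bs)
  expect_gt(online_acc, 0.9)
  expect_gt(offline_acc, 0.9)
})
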