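test_that("linear SVM solves the canonical 1-D toy problem exactly", {
  x <- matrix(c(1, -1), 2, 1)
  fit <- train_linear_svm(x, c(1, -1))
  expect_equal(fit$weights, 1, tolerance = 1e-6)
  expect_equal(fit$bias, 0, tolerance = 1e-6)
  # support vectors sit on the margin
  expect_equal(abs(decision_value(fit, x)), c(1, 1), tolerance = 1e-6)
})

test_that("identical points with opposite labels give a zero weight vector", {
  x <- matrix(1, 2, 3)
  fit <- train_linear_svm(x, c(1, -1))
  expect_equal(fit$weights, rep(0, 3), tolerance = 1e-8)
})

test_that("SVM objective agrees with an exact dual solver on random instances", {
  set.seed(3)
  for (k in 1:6) {
    n <- 20; d <- 4
    x <- matrix(rnorm(n * d), n, d) + rep(rnorm(d), each = n)
    y <- rep(c(1, -1), n / 2)
    x[y == 1, 1] <- x[y == 1, 1] + runif(1, 0, 2)
    fit <- train_linear_svm(x, y, tolerance = 1e-10)
    oracle <- oracle_svm(x, y)
    obj_fit <- svm_primal_objective(fit$weights, fit$bias, x, y)
    obj_oracle <- svm_primal_objective(oracle$weights, oracle$bias, x, y)
    expect_lt(abs(obj_fit - obj_oracle) / obj_oracle, 1e-6)
    # KKT consequence at the optimum: free support vectors lie on the margin
    free <- oracle$alpha > 1e-6 & oracle$alpha < 1 - 1e-6
    if (any(free)) {
      marg <- y[free] * decision_value(oracle, x[free, , drop = FALSE])
      expect_equal(marg, rep(1, sum(free)), tolerance = 1e-6)
    }
  }
})

test_that("decision value is the affine decoder output", {
  m <- list(weights = rep(0, 4), bias = 0)
  expect_equal(decision_value(m, rnorm(4)), 0)
  m2 <- list(weights = c(1, -2), bias = 0)
  x <- c(0.3, 0.4)
  expect_equal(decision_value(m2, 5 * x), 5 * decision_value(m2, x))
  expect_error(decision_value(m2, rnorm(3)), "match")
})

test_that("single-class input is rejected", {
  expect_error(train_linear_svm(matrix(rnorm(8), 4, 2), rep(1, 4)), "both classes")
  expect_error(fit_platt(rnorm(4), rep(1, 4)), "both classes")
})

test_that("Platt fit is symmetric on balanced sign-symmetric decisions", {
  d <- c(-2, -1, 1, 2)
  ab <- fit_platt(d, c(-1, -1, 1, 1))
  expect_equal(ab[["B"]], 0, tolerance = 1e-6)
  expect_lt(ab[["A"]], 0)
  # P at the boundary is exactly 1/2
  m <- list(platt_a = ab[["A"]], platt_b = ab[["B"]])
  expect_equal(platt_probability(m, 0), 0.5, tolerance = 1e-9)
})

test_that("Platt fit recovers known generating parameters", {
  set.seed(21)
  a_true <- -2; b_true <- 0.5
  f <- rnorm(2000, 0, 1.5)
  p <- 1 / (1 + exp(a_true * f + b_true))
  y <- ifelse(runif(2000) < p, 1, -1)
  ab <- fit_platt(f, y)
  expect_equal(ab[["A"]], a_true, tolerance = 0.15)
  expect_equal(ab[["B"]], b_true, tolerance = 0.15)
})

test_that("Platt fit stays finite on separated data and matches the target oracle", {
  f <- c(-3, -2.5, -2, 2, 2.5, 3)
  y <- c(-1, -1, -1, 1, 1, 1)
  ab <- fit_platt(f, y)
  expect_true(all(is.finite(ab)))
  ref <- oracle_platt(f, y)
  expect_equal(ab[["A"]], ref[1], tolerance = 1e-4)
  expect_equal(ab[["B"]], ref[2], tolerance = 1e-4)
  # regularised targets keep probabilities off 0/1
  m <- list(platt_a = ab[["A"]], platt_b = ab[["B"]])
  expect_true(all(platt_probability(m, f) > 0 & platt_probability(m, f) < 1))
})

test_that("Platt fit matches the optimiser oracle on noisy fits", {
  set.seed(33)
  for (k in 1:5) {
    f <- rnorm(60, 0, 2)
    y <- ifelse(runif(60) < 1 / (1 + exp(-1.2 * f + 0.3)), 1, -1)
    if (length(unique(y)) < 2) next
    ab <- fit_platt(f, y)
    ref <- oracle_platt(f, y)
    expect_equal(unname(ab), ref, tolerance = 1e-4)
  }
})

test_that("incremental training sets pool the decoder task and earlier runs", {
  make_tf <- function(r, n = 24, d = 4) structure(
    list(features = matrix(rnorm(n * d, mean = r), n, d),
         labels = rep(c("interoceptive", "exteroceptive"), n / 2),
         run_index = r), class = "trial_features")
  history <- lapply(0:2, make_tf)
  expect_equal(nrow(assemble_training_set(history, 1)$features), 24)
  expect_equal(nrow(assemble_training_set(history, 2)$features), 48)
  ts3 <- assemble_training_set(history, 3)
  expect_equal(nrow(ts3$features), 72)
  # chronological order, no duplication
  expect_equal(ts3$runs, rep(0:2, each = 24))
  expect_equal(ts3$labels[1:4], c(1, -1, 1, -1))
  expect_error(assemble_training_set(history[c(1, 3)], 3), "missing history")
  expect_error(assemble_training_set(history, 4), "target_run")
})

test_that("run decoder training composes SVM and Platt with provenance", {
  toy <- toy_features()
  tf0 <- structure(list(features = toy$x,
                        labels = ifelse(toy$y == 1, "interoceptive", "exteroceptive"),
                        run_index = 0L), class = "trial_features")
  m1 <- train_run_decoder(list(tf0), 1)
  expect_s3_class(m1, "decoder_model")
  expect_equal(m1$trained_on_runs, 0L)
  expect_lte(m1$platt_a, 0)
  # strongly separable: training-set sign accuracy is 1
  expect_equal(sign(decision_value(m1, toy$x)), toy$y)

  # adding new data changes the Platt re-fit
  set.seed(9)
  tf1 <- structure(list(features = toy$x + rnorm(length(toy$x), sd = 0.5),
                        labels = tf0$labels, run_index = 1L),
                   class = "trial_features")
  tf2 <- structure(list(features = toy$x + rnorm(length(toy$x), sd = 2),
                        labels = tf0$labels, run_index = 2L),
                   class = "trial_features")
  m2 <- train_run_decoder(list(tf0, tf1), 2)
  m3 <- train_run_decoder(list(tf0, tf1, tf2), 3)
  expect_equal(m2$trained_on_runs, 0:1)
  expect_equal(m3$trained_on_runs, 0:2)
  expect_false(isTRUE(all.equal(c(m2$platt_a, m2$platt_b),
                                c(m3$platt_a, m3$platt_b))))
})

test_that("calibrated probabilities are reliable at moderate sample size", {
  set.seed(41)
  n <- 2000
  f <- rnorm(n, 0, 2)
  y <- ifelse(runif(n) < 1 / (1 + exp(-1.5 * f)), 1, -1)
  ab <- fit_platt(f, y)
  m <- list(platt_a = ab[["A"]], platt_b = ab[["B"]])
  p <- platt_probability(m, f)
  bins <- cut(p, seq(0, 1, 0.1), include.lowest = TRUE)
  emp <- tapply(y == 1, bins, mean)
  pred <- tapply(p, bins, mean)
  keep <- !is.na(emp) & tapply(rep(1, n), bins, sum) >= 30
  slope <- coef(lm(emp[keep] ~ pred[keep]))[2]
  expect_gt(slope, 0.8)
  expect_lt(slope, 1.2)
})
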