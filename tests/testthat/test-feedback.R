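test_that("NF score reflects the instructed condition", {
  expect_equal(nf_score(0.5, "interoceptive"), 50)
  expect_equal(nf_score(0.5, "exteroceptive"), 50)
  expect_equal(nf_score(0.8, "interoceptive"), 80)
  expect_equal(nf_score(0.8, "exteroceptive"), 20)
  # complementarity
  for (p in c(0, 0.31, 0.77, 1))
    expect_equal(nf_score(p, "interoceptive") + nf_score(p, "exteroceptive"), 100)
  expect_error(nf_score(1.2, "interoceptive"), "probability")
})

test_that("a boundary trial scores 50 and counts as incorrect", {
  m <- structure(list(weights = c(1, -1), bias = 0, c_param = 1,
                      platt_a = -1, platt_b = 0, trained_on_runs = 0L),
                 class = "decoder_model")
  rec <- trial_feedback(m, c(0.5, 0.5), "interoceptive")
  expect_equal(rec$decision, 0)
  expect_equal(rec$probability, 0.5)
  expect_equal(rec$score, 50)
  expect_false(rec$correct)
})

test_that("extreme decision values saturate the score", {
  m <- structure(list(weights = 1, bias = 0, c_param = 1,
                      platt_a = -2, platt_b = 0, trained_on_runs = 0L),
                 class = "decoder_model")
  expect_equal(trial_feedback(m, 500, "interoceptive")$score, 100)
  expect_equal(trial_feedback(m, 500, "exteroceptive")$score, 0)
})

test_that("trial feedback equals the manual composition of its three steps", {
  set.seed(13)
  for (k in 1:10) {
    d <- 5
    m <- structure(list(weights = rnorm(d), bias = rnorm(1), c_param = 1,
                        platt_a = -runif(1, 0.5, 3), platt_b = rnorm(1),
                        trained_on_runs = 0L), class = "decoder_model")
    x <- rnorm(d)
    cond <- sample(c("interoceptive", "exteroceptive"), 1)
    rec <- trial_feedback(m, x, cond)
    f <- sum(m$weights * x) + m$bias
    p <- 1 / (1 + exp(m$platt_a * f + m$platt_b))
    s <- if (cond == "interoceptive") 100 * p else 100 * (1 - p)
    expect_equal(rec$decision, f)
    expect_equal(rec$probability, p)
    expect_equal(rec$score, s)
    expect_equal(rec$correct, s > 50)
  }
})

test_that("vectorised run records equal per-trial feedback", {
  set.seed(14)
  d <- 6
  m <- structure(list(weights = rnorm(d), bias = 0.2, c_param = 1,
                      platt_a = -1.3, platt_b = 0.1, trained_on_runs = 0L),
                 class = "decoder_model")
  tf <- structure(list(features = matrix(rnorm(8 * d), 8, d),
                       labels = rep(c("interoceptive", "exteroceptive"), 4),
                       run_index = 2L), class = "trial_features")
  recs <- feedback_records(m, tf)
  for (i in 1:8) {
    one <- trial_feedback(m, tf$features[i, ], tf$labels[i],
                          run_index = 2L, trial_index = i - 1L)
    expect_equal(recs[i, ], one, ignore_attr = TRUE)
  }
})

test_that("run summaries count strict successes exactly", {
  recs <- data.frame(run_index = 1L, trial_index = 0:3,
                     condition = rep(c("interoceptive", "exteroceptive"), 2),
                     decision = 0, probability = 0.5,
                     score = c(50, 49.999, 50.001, 80),
                     correct = c(FALSE, FALSE, TRUE, TRUE))
  s <- run_summary(recs)
  expect_equal(s$classification_accuracy, mean(recs$score > 50))
  expect_equal(s$classification_accuracy, 0.5)
  expect_equal(s$mean_score, mean(recs$score))
})

test_that("learning effect is final-run performance over the early baseline", {
  expect_equal(learning_effect(50, 50, 50), 0)
  expect_equal(learning_effect(40, 60, 70), 20)
  # the published sham displayed-score run means
  expect_equal(learning_effect(50.850, 54.839, 56.174), 3.3295)
  # affine contract: shifting run 3 and the early-run mean equally is neutral
  le <- learning_effect(42, 58, 61)
  expect_equal(learning_effect(42 + 7, 58 + 7, 61 + 7), le)
  # but it is not invariant to shifting a single run
  expect_false(learning_effect(42 + 7, 58, 61) == le)
})
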