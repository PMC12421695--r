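test_that("degenerate generator inputs give a constant baseline matrix", {
  p <- acquisition_params(n_voxels = 4L)
  sch <- build_schedule("regulation", p, 1)
  sp <- subject_params("null", "NF", learnability = 0,
                       pattern_intero = rep(0, 4), pattern_extero = rep(0, 4),
                       noise_sd = 0, drift_amplitude = 0, baseline_level = 500)
  ts <- simulate_run(sch, sp, 1, seed = 1, params = p)
  expect_equal(ts$data, matrix(500, sch$n_volumes, 4))
})

test_that("learnability scales patterns only for NF subjects across runs", {
  p <- acquisition_params(n_voxels = 6L)
  sch <- build_schedule("regulation", p, 1)
  mk <- function(group, lam) subject_params("s", group, learnability = lam,
    pattern_intero = c(1, 0, -1, 0.5, 0, 0), pattern_extero = c(0, 1, 0, -0.5, 1, 0),
    noise_sd = 0, drift_amplitude = 0)
  base <- simulate_run(sch, mk("NF", 0), 1, seed = 2, params = p)$data
  # lambda = 0: identical signal in every run
  r3 <- simulate_run(sch, mk("NF", 0), 3, seed = 2, params = p)$data
  expect_equal(base, r3)
  # NF with lambda > 0: amplitude grows as 1 + lambda * run
  nf3 <- simulate_run(sch, mk("NF", 0.5), 3, seed = 2, params = p)$data
  expect_equal(nf3 - 1000, (1 + 0.5 * 3) * (base - 1000), tolerance = 1e-10)
  # Sham: drawn lambda never realised
  sh3 <- simulate_run(sch, mk("Sham", 0.5), 3, seed = 2, params = p)$data
  expect_equal(sh3, base)
})

test_that("runs are deterministic in the seed", {
  p <- acquisition_params(n_voxels = 5L)
  sch <- build_schedule("decoder_training", p, 0)
  sp <- subject_params("s", "NF", 0.2, rnorm(5), rnorm(5))
  a <- simulate_run(sch, sp, 0, seed = 77, params = p)
  b <- simulate_run(sch, sp, 0, seed = 77, params = p)
  cc <- simulate_run(sch, sp, 0, seed = 78, params = p)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, cc$data))
  expect_equal(nrow(a$data), sch$n_volumes)
  expect_true(all(is.finite(a$data)))
})

test_that("cohorts have the configured arm sizes and reproduce from the seed", {
  cfg <- tiny_config()
  co <- simulate_cohort(2, 2, cfg, seed = 5, simulate_runs = FALSE)
  expect_length(co, 4)
  groups <- vapply(co, function(s) s$params$group, character(1))
  expect_equal(groups, c("NF", "NF", "Sham", "Sham"))
  co2 <- simulate_cohort(2, 2, cfg, seed = 5, simulate_runs = FALSE)
  expect_equal(co, co2)
  # empty NF arm is allowed at generation time
  co0 <- simulate_cohort(0, 2, cfg, seed = 5, simulate_runs = FALSE)
  expect_length(co0, 2)
  expect_true(all(vapply(co0, function(s) s$params$group, character(1)) == "Sham"))
})

test_that("default cohort draws a non-learner mixture in the NF arm", {
  cfg <- cohort_config(params = acquisition_params(n_voxels = 10L))
  co <- simulate_cohort(40, 0, cfg, seed = 31, simulate_runs = FALSE)
  lam <- vapply(co, function(s) s$params$learnability, numeric(1))
  expect_gt(mean(lam == 0), 0.2)   # ~40% non-learners
  expect_lt(mean(lam == 0), 0.6)
  expect_true(all(lam >= 0))
})

test_that("heartbeat sessions cover the six durations and score correctly", {
  sp <- subject_params("s", "NF", 0.5, rnorm(5), rnorm(5),
                       perception_fraction_pre = 1)
  hb <- simulate_heartbeat_session(sp, "pre", 0, seed = 3,
                                   count_jitter_sd = 0, report_noise_sd = 0)
  expect_equal(hb$duration_seconds, c(15, 25, 35, 45, 55, 65))
  # perfect perception, no noise: reported = recorded, accuracy 1
  expect_equal(hb$reported_beats, hb$recorded_beats)
  expect_equal(interoceptive_accuracy(hb), 1)
  expect_error(simulate_heartbeat_session(sp, "pre", 0.2), "must be 0")
})

test_that("positive coupling raises post-session accuracy for NF subjects", {
  sp <- subject_params("s", "NF", 1, rnorm(5), rnorm(5),
                       perception_fraction_pre = 0.6, behaviour_coupling = 0.5)
  sh <- sp; sh$group <- "Sham"
  gain_nf <- gain_sham <- numeric(40)
  for (k in 1:40) {
    pre <- simulate_heartbeat_session(sp, "pre", 0, seed = 100 + k)
    post <- simulate_heartbeat_session(sp, "post", 0.3, seed = 200 + k)
    gain_nf[k] <- interoceptive_accuracy(post) - interoceptive_accuracy(pre)
    post_s <- simulate_heartbeat_session(sh, "post", 0.3, seed = 200 + k)
    gain_sham[k] <- interoceptive_accuracy(post_s) - interoceptive_accuracy(pre)
  }
  expect_gt(mean(gain_nf), 0.05)          # coupling acts
  expect_lt(abs(mean(gain_sham)), 0.05)   # contingency: no coupling for sham
})

test_that("a high-SNR subject is decodable end to end", {
  p <- acquisition_params(n_voxels = 20L)
  sch <- build_schedule("regulation", p, 1)
  set.seed(55)
  sp <- subject_params("hi", "NF", 0,
                       pattern_intero = rnorm(20, sd = 2),
                       pattern_extero = rnorm(20, sd = 2),
                       noise_sd = 1)
  ts <- simulate_run(sch, sp, 1, seed = 9, params = p)
  psc <- percent_signal_change(ts)
  bs <- estimate_trial_betas(psc, build_beta_series_design(sch, p))
  expect_gte(two_fold_cv_accuracy(bs), 0.95)
})
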