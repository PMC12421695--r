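#' Run one subject through the full neurofeedback session
#'
#' Executes the complete closed loop for a simulated subject: percent-signal-
#' change preprocessing and feature extraction of the decoder training task,
#' per-run incremental decoder retraining, per-trial feedback computation,
#' sham score generation (sham arm), offline beta-series MVPA, and the pre/
#' post heartbeat counting sessions.
#'
#' True feedback scores are always computed from the subject's brain data —
#' also in the sham arm, where they are never "displayed"; sham subjects'
#' displayed scores come from the sham generator instead and are therefore
#' statistically independent of their brain activity. Behavioural coupling
#' acts through the *displayed* classification-accuracy learning effect (what
#' the subject experienced); in the sham arm the coupling is zero.
#'
#' @param subject A `simulated_subject` from [simulate_cohort()].
#' @param sham_model A [fit_sham_model()] object; required iff the subject is
#'   in the sham group.
#' @param config The [cohort_config()] used to simulate the cohort.
#' @param seed Integer seed for the session-level randomness (sham sampling,
#'   heartbeat sessions). Defaults to the subject's own seed.
#' @param include_mvpa Run the offline beta-series MVPA per run. Default
#'   `TRUE`.
#' @return A `session_result` list: `subject_id`, `group`, `records` (true
#'   per-trial feedback), `true_summaries` and `displayed_summaries` (3-row
#'   data frames), `sham_scores` (3 x 24 matrix or `NULL`), `offline_ca`
#'   (length-4 vector, decoder task first, or `NULL`), `heartbeat_pre`,
#'   `heartbeat_post`, and `outcome` (one-row data frame of subject-level
#'   measures).
#' @export
run_subject_session <- function(subject, sham_model = NULL,
                                config = cohort_config(),
                                seed = subject$seed,
                                include_mvpa = TRUE) {
  sp <- subject$params
  if (sp$group == "Sham" && is.null(sham_model))
    stop("sham subjects require a sham_model")
  acq <- config$params
  schedules <- subject$schedules
  shift <- config$hemodynamic_shift

  runs <- subject$runs
  lazy <- is.null(runs)
  if (!lazy && length(runs) != 4) stop("expected 4 simulated runs")

  get_run <- function(r, gain = NULL) {
    if (!lazy && is.null(gain)) return(runs[[r + 1]])
    simulate_run(schedules[[r + 1]], sp, run_index = r,
                 seed = run_seed(subject$seed, r), params = acq, gain = gain)
  }

  run0 <- get_run(0)
  psc0 <- percent_signal_change(run0)
  history <- list(extract_trial_features(psc0, schedules[[1]], acq, shift))
  psc_runs <- list(psc0)

  set.seed(as.integer(seed %% 2147483647))
  sham_scores <- if (sp$group == "Sham")
    generate_sham_session(sham_model) else NULL

  records <- list()
  true_sum <- vector("list", 3)
  disp_sum <- vector("list", 3)
  cum_feedback <- 0  # feedback-driven learning state
  for (r in 1:3) {
    model <- train_run_decoder(history, r)
    gain <- NULL
    if (config$learning_mode == "feedback_driven" && sp$group == "NF")
      gain <- 1 + sp$learnability * cum_feedback
    run_ts <- get_run(r, gain = gain)
    psc <- percent_signal_change(run_ts)
    feats <- extract_trial_features(psc, schedules[[r + 1]], acq, shift)
    recs <- feedback_records(model, feats, run_index = r)
    records[[r]] <- recs
    true_sum[[r]] <- run_summary(recs)
    if (sp$group == "Sham") {
      disp <- recs
      disp$score <- sham_scores[r, ]
      disp$correct <- disp$score > 50
      disp$probability <- NA_real_
      disp$decision <- NA_real_
      disp_sum[[r]] <- run_summary(disp)
    } else {
      disp_sum[[r]] <- true_sum[[r]]
    }
    cum_feedback <- cum_feedback + (mean(disp_sum[[r]]$mean_score) - 50) / 50
    history <- c(history, list(feats))
    psc_runs <- c(psc_runs, list(psc))
  }
  records <- do.call(rbind, records)
  true_summaries <- do.call(rbind, true_sum)
  displayed_summaries <- do.call(rbind, disp_sum)

  offline_ca <- NULL
  if (include_mvpa) {
    offline_ca <- vapply(0:3, function(r) {
      des <- build_beta_series_design(schedules[[r + 1]], acq,
                                      n_volumes = nrow(psc_runs[[r + 1]]))
      bs <- estimate_trial_betas(psc_runs[[r + 1]], des, run_index = r)
      two_fold_cv_accuracy(bs)
    }, numeric(1))
  }

  le_score <- learning_effect(displayed_summaries$mean_score[1],
                              displayed_summaries$mean_score[2],
                              displayed_summaries$mean_score[3])
  le_ca <- learning_effect(displayed_summaries$classification_accuracy[1],
                           displayed_summaries$classification_accuracy[2],
                           displayed_summaries$classification_accuracy[3])

  hb_pre <- simulate_heartbeat_session(sp, "pre", 0,
                                       seed = run_seed(seed, 11L),
                                       count_jitter_sd = config$count_jitter_sd,
                                       report_noise_sd = config$report_noise_sd)
  hb_post <- simulate_heartbeat_session(sp, "post", le_ca,
                                        seed = run_seed(seed, 12L),
                                        count_jitter_sd = config$count_jitter_sd,
                                        report_noise_sd = config$report_noise_sd)
  bpm_pre <- bpm_summary(hb_pre); bpm_post <- bpm_summary(hb_post)
  ia_pre <- interoceptive_accuracy(hb_pre)
  ia_post <- interoceptive_accuracy(hb_post)

  outcome <- data.frame(
    subject_id = sp$subject_id, group = sp$group,
    le_score = le_score, le_ca = le_ca,
    true_le_score = learning_effect(true_summaries$mean_score[1],
                                    true_summaries$mean_score[2],
                                    true_summaries$mean_score[3]),
    true_le_ca = learning_effect(true_summaries$classification_accuracy[1],
                                 true_summaries$classification_accuracy[2],
                                 true_summaries$classification_accuracy[3]),
    ia_pre = ia_pre, ia_post = ia_post, delta_ia = ia_post - ia_pre,
    confidence_pre = mean(hb_pre$confidence),
    confidence_post = mean(hb_post$confidence),
    bpm_actual_pre = bpm_pre[["actual_bpm"]],
    bpm_actual_post = bpm_post[["actual_bpm"]],
    bpm_perceived_pre = bpm_pre[["perceived_bpm"]],
    bpm_perceived_post = bpm_post[["perceived_bpm"]],
    stringsAsFactors = FALSE
  )

  structure(list(subject_id = sp$subject_id, group = sp$group,
                 records = records, true_summaries = true_summaries,
                 displayed_summaries = displayed_summaries,
                 sham_scores = sham_scores, offline_ca = offline_ca,
                 heartbeat_pre = hb_pre, heartbeat_post = hb_post,
                 outcome = outcome),
            class = "session_result")
}

#' Simulate and analyse a full cohort experiment
#'
#' Simulates the cohort, runs every NF-arm session, fits the sham feedback
#' model on the NF arm's displayed scores (success rates default to the
#' original study's printed per-run rates unless `estimate_rates`), runs
#' every sham-arm session against it, and aggregates: subject outcomes,
#' group-level statistics, the sham-validation correlation between displayed
#' sham scores and concurrently computed true scores, and (optionally)
#' offline MVPA accuracies.
#'
#' @param config A [cohort_config()] object.
#' @param seed Integer master seed; the whole report is a deterministic
#'   function of it.
#' @param include_mvpa Run the offline beta-series MVPA for every subject
#'   (the slowest step). Default `TRUE`.
#' @param estimate_rates Re-estimate the sham success rates from the
#'   simulated NF arm instead of using the printed study values.
#' @return A `cohort_report` list: `outcomes` (data frame, one row per
#'   subject), `group_stats` ([group_statistics()] report), `sham_validation`
#'   (pooled displayed-vs-true correlation and sham learning-effect tests),
#'   `run_means` (per group x run displayed score/CA means), `offline_ca`
#'   (per-subject matrix or `NULL`), `sessions` (list of `session_result`),
#'   `sham_model`, `seed`.
#' @export
run_cohort_experiment <- function(config = cohort_config(), seed = 1L,
                                  include_mvpa = TRUE,
                                  estimate_rates = FALSE) {
  cohort <- simulate_cohort(config$n_nf, config$n_sham, config, seed = seed,
                            simulate_runs = FALSE)
  is_nf <- vapply(cohort, function(s) s$params$group == "NF", logical(1))

  sessions <- vector("list", length(cohort))
  for (i in which(is_nf))
    sessions[[i]] <- run_subject_session(cohort[[i]], NULL, config,
                                         include_mvpa = include_mvpa)

  sham_model <- NULL
  if (any(!is_nf)) {
    if (!any(is_nf))
      stop("a sham arm requires at least one NF subject to fit the sham model")
    nf_scores_by_run <- lapply(1:3, function(r)
      lapply(sessions[is_nf], function(s)
        s$records$score[s$records$run_index == r]))
    sham_model <- fit_sham_model(nf_scores_by_run,
                                 estimate_rates = estimate_rates)
    for (i in which(!is_nf))
      sessions[[i]] <- run_subject_session(cohort[[i]], sham_model, config,
                                           include_mvpa = include_mvpa)
  }

  outcomes <- do.call(rbind, lapply(sessions, function(s) s$outcome))
  # group statistics need at least 3 subjects per arm (correlations)
  group_stats <- if (sum(is_nf) >= 3 && sum(!is_nf) >= 3)
    group_statistics(outcomes)

  sham_validation <- NULL
  if (any(!is_nf)) {
    disp <- unlist(lapply(sessions[!is_nf], function(s) t(s$sham_scores)))
    true <- unlist(lapply(sessions[!is_nf], function(s) s$records$score))
    sham_le <- outcomes$le_score[outcomes$group == "Sham"]
    sham_true_le <- outcomes$true_le_score[outcomes$group == "Sham"]
    sham_validation <- list(
      displayed_vs_true = pearson_ci(disp, true),
      n_trials = length(disp),
      apparent_le = if (length(sham_le) >= 2) one_sample_t(sham_le),
      true_le = if (length(sham_true_le) >= 2) one_sample_t(sham_true_le)
    )
  }

  run_means <- do.call(rbind, lapply(c("NF", "Sham"), function(g) {
    sel <- sessions[vapply(sessions, function(s) s$group == g, logical(1))]
    if (!length(sel)) return(NULL)
    do.call(rbind, lapply(1:3, function(r) data.frame(
      group = g, run_index = r,
      mean_score = mean(vapply(sel, function(s)
        s$displayed_summaries$mean_score[r], numeric(1))),
      mean_ca = mean(vapply(sel, function(s)
        s$displayed_summaries$classification_accuracy[r], numeric(1)))
    )))
  }))

  offline_ca <- if (include_mvpa)
    do.call(rbind, lapply(sessions, function(s) s$offline_ca))

  structure(list(outcomes = outcomes, group_stats = group_stats,
                 sham_validation = sham_validation, run_means = run_means,
                 offline_ca = offline_ca, sessions = sessions,
                 sham_model = sham_model, seed = seed),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  n <- table(x$outcomes$group)
  cat(sprintf("<cohort_report> %d subjects (%s)\n", nrow(x$outcomes),
              paste(sprintf("%s = %d", names(n), n), collapse = ", ")))
  if (!is.null(x$group_stats)) {
    g <- x$group_stats
    cat(sprintf("  NF  learning effect (score): %.3f (t = %.3f, p = %.4f)\n",
                g$NF$t_le_score$mean, g$NF$t_le_score$t, g$NF$t_le_score$p))
    cat(sprintf("  NF  LE(CA) vs delta-accuracy r = %.3f [%.3f, %.3f]\n",
                g$NF$cor_ca$r, g$NF$cor_ca$ci[1], g$NF$cor_ca$ci[2]))
  }
  if (!is.null(x$sham_validation))
    cat(sprintf("  sham displayed vs true score r = %.4f over %d trials\n",
                x$sham_validation$displayed_vs_true$r, x$sham_validation$n_trials))
  invisible(x)
}
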