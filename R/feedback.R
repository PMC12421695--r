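#' Neurofeedback score with condition inversion
#'
#' `100 * P(y = 1 | x)` on interoceptive blocks and `100 * (1 - P(y = 1 | x))`
#' on exteroceptive blocks, so that the displayed score always reflects the
#' decoder's confidence in the *instructed* attentional state. A score of 50
#' is an ambiguous classification.
#'
#' @param probability Platt-calibrated interoceptive probability in `[0, 1]`.
#' @param condition `"interoceptive"` or `"exteroceptive"`.
#' @return Score in `[0, 100]`.
#' @export
nf_score <- function(probability, condition = c("interoceptive", "exteroceptive")) {
  condition <- match.arg(condition)
  if (any(probability < 0 | probability > 1)) stop("probability outside [0, 1]")
  if (condition == "interoceptive") 100 * probability else 100 * (1 - probability)
}

#' Feedback record for one trial
#'
#' Runs the full per-trial feedback computation: decision value, Platt
#' probability, condition-inverted score, and correctness. A trial counts as
#' correctly classified only when its score strictly exceeds 50 (a score of
#' exactly 50 is ambiguous and counts as incorrect).
#'
#' @param model A `decoder_model` ([train_run_decoder()]).
#' @param feature Feature vector of the trial.
#' @param condition Instructed condition of the trial.
#' @param run_index,trial_index Bookkeeping indices stored in the record.
#' @return One-row data frame with columns `run_index`, `trial_index`,
#'   `condition`, `decision`, `probability`, `score`, `correct`.
#' @export
trial_feedback <- function(model, feature,
                           condition = c("interoceptive", "exteroceptive"),
                           run_index = NA_integer_, trial_index = NA_integer_) {
  condition <- match.arg(condition)
  f <- decision_value(model, feature)
  p <- platt_probability(model, f)
  s <- nf_score(p, condition)
  data.frame(run_index = run_index, trial_index = trial_index,
             condition = condition, decision = f, probability = p,
             score = s, correct = s > 50, stringsAsFactors = FALSE)
}

#' Feedback records for a whole run
#'
#' Vectorised equivalent of calling [trial_feedback()] on every trial of a
#' run's feature set.
#'
#' @param model A `decoder_model`.
#' @param feats A `trial_features` object ([extract_trial_features()]).
#' @param run_index Run index stored in the records.
#' @return Data frame of feedback records, one row per trial.
#' @export
feedback_records <- function(model, feats, run_index = feats$run_index) {
  f <- decision_value(model, feats$features)
  p <- platt_probability(model, f)
  s <- ifelse(feats$labels == "interoceptive", 100 * p, 100 * (1 - p))
  data.frame(run_index = run_index,
             trial_index = seq_along(f) - 1L,
             condition = feats$labels, decision = f, probability = p,
             score = s, correct = s > 50, stringsAsFactors = FALSE)
}

#' Summarise a run's feedback records
#'
#' @param records Data frame of [trial_feedback()] rows (one run).
#' @return One-row data frame: `run_index`, `mean_score`,
#'   `classification_accuracy` (fraction of trials with score > 50),
#'   `mean_score_intero`, `mean_score_extero`, `ca_intero`, `ca_extero`.
#' @export
run_summary <- function(records) {
  stopifnot(nrow(records) > 0)
  int <- records$condition == "interoceptive"
  data.frame(
    run_index = records$run_index[1],
    mean_score = mean(records$score),
    classification_accuracy = mean(records$score > 50),
    mean_score_intero = mean(records$score[int]),
    mean_score_extero = mean(records$score[!int]),
    ca_intero = mean(records$score[int] > 50),
    ca_extero = mean(records$score[!int] > 50)
  )
}

#' Learning effect across the three regulation runs
#'
#' `Run 3 - (Run 1 + Run 2) / 2`: the final run against the average of the
#' first two as baseline, applicable to both mean-score and
#' classification-accuracy series. Vectorised over subjects.
#'
#' @param run1_mean,run2_mean,run3_mean Per-run summary values.
#' @return The learning effect(s).
#' @export
learning_effect <- function(run1_mean, run2_mean, run3_mean) {
  run3_mean - (run1_mean + run2_mean) / 2
}
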