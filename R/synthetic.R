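#' Cohort simulation configuration
#'
#' Defaults describe the emulated study: 28 neurofeedback (NF) and 26 sham
#' participants, a 150-voxel right-insula ROI at TR = 2 s, condition-specific
#' voxel patterns of about 1 percent signal amplitude against autocorrelated
#' noise, a 40 percent non-learner fraction in the NF arm, and behavioural
#' coupling between regulation learning and heartbeat-counting gains.
#'
#' Amplitude/noise defaults are calibrated so that run-level online
#' classification accuracy starts near chance and rises to the low 0.6s for
#' NF learners, the operating range of the emulated experiment; the
#' behavioural coupling is calibrated so the NF-arm correlation between the
#' classification-accuracy learning effect and the change in interoceptive
#' accuracy sits near 0.55.
#'
#' @param n_nf,n_sham Group sizes.
#' @param params An [acquisition_params()] object.
#' @param pattern_sd Amplitude sd of an informative voxel's activation, in
#'   percent signal change.
#' @param pattern_sparsity Fraction of ROI voxels that are informative
#'   (carry a condition-specific response); the remainder respond to neither
#'   condition, as in real ROIs where the discriminative pattern lives in a
#'   subset of voxels.
#' @param noise_sd Marginal sd of the AR(1) voxel noise, percent units.
#' @param ar1_rho Lag-1 autocorrelation of the voxel noise.
#' @param drift_amplitude Amplitude of the sinusoidal slow drift (percent),
#'   shared across voxels; period fixed at 128 s.
#' @param baseline_level Raw-signal baseline level (arbitrary scanner units).
#' @param nonlearner_fraction Fraction of NF subjects with (near-)zero
#'   learnability.
#' @param lambda_mean,lambda_sd Mean/sd of the learnability draw for
#'   learners (truncated at 0): per-run fractional growth of pattern
#'   separability under contingent feedback.
#' @param behaviour_coupling Gain linking the displayed classification-
#'   accuracy learning effect to the post-training heartbeat perception
#'   fraction (NF arm only).
#' @param heart_rate_mean,heart_rate_sd Pre-session heart rate distribution
#'   (beats/min).
#' @param heart_rate_drop_mean,heart_rate_drop_sd Session-related decrease of
#'   actual heart rate (both groups).
#' @param perception_range Range of the uniform draw of the pre-session
#'   heartbeat perception fraction.
#' @param count_jitter_sd Sd of the jitter on recorded beat counts.
#' @param report_noise_sd Sd of the integer noise on reported beat counts.
#' @param learning_mode `"contingent"`: pattern separability of NF subjects
#'   grows as `1 + lambda * run_index` (zero growth in the sham arm);
#'   `"feedback_driven"`: growth accrues in proportion to the feedback
#'   scores actually received in earlier runs (NF arm only).
#' @param hemodynamic_shift Feature-window shift in volumes.
#' @param first_condition Condition of the first block in every run.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_nf = 28L, n_sham = 26L,
                          params = acquisition_params(),
                          pattern_sd = 1.0,
                          pattern_sparsity = 0.05,
                          noise_sd = 45,
                          ar1_rho = 0.3,
                          drift_amplitude = 1.0,
                          baseline_level = 1000,
                          nonlearner_fraction = 0.4,
                          lambda_mean = 5.0, lambda_sd = 1.5,
                          behaviour_coupling = 0.15,
                          heart_rate_mean = 70, heart_rate_sd = 8,
                          heart_rate_drop_mean = 2, heart_rate_drop_sd = 1.5,
                          perception_range = c(0.45, 0.95),
                          count_jitter_sd = 1,
                          report_noise_sd = 2,
                          learning_mode = c("contingent", "feedback_driven"),
                          hemodynamic_shift = 2L,
                          first_condition = "interoceptive") {
  learning_mode <- match.arg(learning_mode)
  structure(as.list(environment()), class = "cohort_config")
}

#' Per-subject simulation parameters
#'
#' Validates and bundles one simulated subject's ground-truth parameters.
#' `pattern_intero` / `pattern_extero` are the condition-specific voxel
#' activation patterns (percent signal change); `learnability` is the
#' per-run fractional growth of pattern separability realised only under
#' contingent feedback.
#'
#' @param subject_id Label.
#' @param group `"NF"` or `"Sham"`.
#' @param learnability Non-negative scalar.
#' @param pattern_intero,pattern_extero Voxel-length amplitude vectors.
#' @param noise_sd,ar1_rho,drift_amplitude,baseline_level Noise model (see
#'   [cohort_config()]).
#' @param heart_rate_pre,heart_rate_post Actual heart rates (beats/min).
#' @param perception_fraction_pre Baseline fraction of heartbeats perceived,
#'   in `[0, 1]`.
#' @param behaviour_coupling Coupling of regulation learning to perception
#'   gain.
#' @param confidence_pre Baseline confidence rating, `[0, 100]`.
#' @return A list of class `subject_params`.
#' @export
subject_params <- function(subject_id, group = c("NF", "Sham"), learnability,
                           pattern_intero, pattern_extero,
                           noise_sd = 45, ar1_rho = 0.3,
                           drift_amplitude = 1.0, baseline_level = 1000,
                           heart_rate_pre = 70, heart_rate_post = 68,
                           perception_fraction_pre = 0.7,
                           behaviour_coupling = 0.15,
                           confidence_pre = 60) {
  group <- match.arg(group)
  stopifnot(learnability >= 0, noise_sd >= 0, ar1_rho >= 0, ar1_rho < 1,
            perception_fraction_pre >= 0, perception_fraction_pre <= 1,
            length(pattern_intero) == length(pattern_extero),
            heart_rate_pre > 0, heart_rate_post > 0)
  structure(list(subject_id = subject_id, group = group,
                 learnability = learnability,
                 pattern_intero = pattern_intero,
                 pattern_extero = pattern_extero,
                 noise_sd = noise_sd, ar1_rho = ar1_rho,
                 drift_amplitude = drift_amplitude,
                 baseline_level = baseline_level,
                 heart_rate_pre = heart_rate_pre,
                 heart_rate_post = heart_rate_post,
                 perception_fraction_pre = perception_fraction_pre,
                 behaviour_coupling = behaviour_coupling,
                 confidence_pre = confidence_pre),
            class = "subject_params")
}

#' Simulate one ROI run
#'
#' Generates a volumes x voxels raw-signal matrix for one run:
#' `baseline_level * (1 + (s + noise + drift) / 100)`, where `s(t, v)` places
#' each condition's voxel pattern as a 10-second boxcar over that condition's
#' regulation periods, convolved with the canonical HRF, and scaled by the
#' learning gain (`1 + learnability * run_index` for NF subjects under
#' contingent feedback, 1 otherwise — pass `gain` to override); `noise` is
#' voxel-wise AR(1) with the subject's marginal sd; `drift` is a
#' 128-second-period sinusoid with random phase, shared across voxels.
#'
#' @param schedule A [build_schedule()] object.
#' @param subject A [subject_params()] object.
#' @param run_index Run position (0 = decoder task, 1-3 = regulation).
#' @param seed Integer seed; the run is a deterministic function of it.
#' @param params An [acquisition_params()] object.
#' @param gain Optional explicit pattern gain overriding the contingent rule.
#' @return A `roi_timeseries` object: `data` (volumes x voxels), `params`,
#'   `schedule`.
#' @export
simulate_run <- function(schedule, subject, run_index = schedule$run_index,
                         seed = 1L, params = acquisition_params(),
                         gain = NULL) {
  stopifnot(inherits(schedule, "run_schedule"), inherits(subject, "subject_params"))
  n_vol <- schedule$n_volumes
  n_vox <- length(subject$pattern_intero)
  tr <- params$tr_seconds
  if (is.null(gain))
    gain <- if (subject$group == "NF") 1 + subject$learnability * run_index else 1

  b <- schedule$blocks
  on <- regulation_onset_seconds(b)
  off <- on + b$regulation_seconds
  int <- b$condition == "interoceptive"
  reg_i <- hrf_regressor(on[int], off[int], n_vol, tr)
  reg_e <- hrf_regressor(on[!int], off[!int], n_vol, tr)
  s <- gain * (outer(reg_i, subject$pattern_intero) +
               outer(reg_e, subject$pattern_extero))

  set.seed(as.integer(seed %% 2147483647))
  noise <- matrix(0, n_vol, n_vox)
  if (subject$noise_sd > 0) {
    rho <- subject$ar1_rho
    innov_sd <- subject$noise_sd * sqrt(1 - rho^2)
    noise[1, ] <- stats::rnorm(n_vox, 0, subject$noise_sd)
    for (t in 2:n_vol)
      noise[t, ] <- rho * noise[t - 1, ] + stats::rnorm(n_vox, 0, innov_sd)
  }
  drift <- if (subject$drift_amplitude > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    subject$drift_amplitude * sin(2 * pi * (seq_len(n_vol) - 1) * tr / 128 + phase)
  } else rep(0, n_vol)

  data <- subject$baseline_level * (1 + (s + noise + drift) / 100)
  structure(list(data = data, params = params, schedule = schedule),
            class = "roi_timeseries")
}

# Draw one subject's ground-truth parameters from the population config.
# Consumes the current RNG stream.
draw_subject_params <- function(id, group, config) {
  n_vox <- config$params$n_voxels
  lambda <- if (stats::runif(1) < config$nonlearner_fraction) 0
            else max(0, stats::rnorm(1, config$lambda_mean, config$lambda_sd))
  hr_pre <- max(45, stats::rnorm(1, config$heart_rate_mean, config$heart_rate_sd))
  hr_post <- max(40, hr_pre - stats::rnorm(1, config$heart_rate_drop_mean,
                                           config$heart_rate_drop_sd))
  informative <- stats::runif(n_vox) < config$pattern_sparsity
  subject_params(
    subject_id = id, group = group, learnability = lambda,
    pattern_intero = stats::rnorm(n_vox, 0, config$pattern_sd) * informative,
    pattern_extero = stats::rnorm(n_vox, 0, config$pattern_sd) * informative,
    noise_sd = config$noise_sd, ar1_rho = config$ar1_rho,
    drift_amplitude = config$drift_amplitude,
    baseline_level = config$baseline_level,
    heart_rate_pre = hr_pre, heart_rate_post = hr_post,
    perception_fraction_pre = stats::runif(1, config$perception_range[1],
                                           config$perception_range[2]),
    behaviour_coupling = config$behaviour_coupling,
    confidence_pre = stats::runif(1, 30, 80)
  )
}

#' Simulate a full cohort
#'
#' Draws per-subject ground-truth parameters (learnability mixture, voxel
#' patterns, heart rates, perception fractions) and, optionally, all four
#' runs of ROI data per subject (decoder task + 3 regulation runs). Sham
#' subjects draw a learnability value like NF subjects but it is never
#' realised (feedback contingency: separability growth requires contingent
#' feedback). Fully reproducible from `seed`; per-subject x run seeds are
#' derived from a subject-level seed table.
#'
#' @param n_nf,n_sham Group sizes. Defaults 28 and 26.
#' @param config A [cohort_config()] object.
#' @param seed Integer master seed.
#' @param simulate_runs If `TRUE` (default), attach the 4 `roi_timeseries`
#'   runs per subject; if `FALSE`, only parameters and seeds (runs can be
#'   regenerated with [simulate_run()]).
#' @return List of `simulated_subject` objects: `params`, `seed`,
#'   `schedules` (list of 4), and `runs` (when simulated).
#' @export
simulate_cohort <- function(n_nf = 28L, n_sham = 26L, config = cohort_config(),
                            seed = 1L, simulate_runs = TRUE) {
  stopifnot(n_nf >= 0, n_sham >= 0)
  n <- n_nf + n_sham
  schedules <- session_schedules(config)
  set.seed(as.integer(seed %% 2147483647))
  subject_seeds <- sample.int(2000000000L, max(n, 1))
  groups <- c(rep("NF", n_nf), rep("Sham", n_sham))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(subject_seeds[i])
    sp <- draw_subject_params(sprintf("sub-%02d", i), groups[i], config)
    subj <- structure(list(params = sp, seed = subject_seeds[i],
                           schedules = schedules, runs = NULL),
                      class = "simulated_subject")
    if (simulate_runs && config$learning_mode == "contingent")
      subj$runs <- lapply(0:3, function(r)
        simulate_run(schedules[[r + 1]], sp, run_index = r,
                     seed = run_seed(subject_seeds[i], r),
                     params = config$params))
    out[[i]] <- subj
  }
  out
}

# Session schedule set: decoder task then three regulation runs.
session_schedules <- function(config) {
  c(list(build_schedule("decoder_training", config$params, 0,
                        first_condition = config$first_condition)),
    lapply(1:3, function(r)
      build_schedule("regulation", config$params, r,
                     first_condition = config$first_condition)))
}

# Counter-based per-run / per-task seed derivation (kept below 2^31).
run_seed <- function(subject_seed, counter) {
  as.integer((as.numeric(subject_seed) * 31 + 1000003 * (counter + 1)) %% 2147483629)
}

#' Simulate one heartbeat counting session
#'
#' Six trials with durations 15, 25, 35, 45, 55 and 65 seconds. Recorded
#' beats follow the session's heart rate with small jitter; reported beats
#' are the recorded count scaled by the subject's perception fraction —
#' raised by `behaviour_coupling * learning_effect` for NF subjects after
#' training — plus integer reporting noise.
#'
#' @param subject A [subject_params()] object.
#' @param session `"pre"` or `"post"`.
#' @param learning_effect Displayed classification-accuracy learning effect;
#'   must be 0 for the pre session.
#' @param seed Integer seed.
#' @param count_jitter_sd,report_noise_sd Noise magnitudes (beats).
#' @return Data frame of 6 rows: `duration_seconds`, `recorded_beats`,
#'   `reported_beats`, `confidence`.
#' @export
simulate_heartbeat_session <- function(subject, session = c("pre", "post"),
                                       learning_effect = 0, seed = 1L,
                                       count_jitter_sd = 1,
                                       report_noise_sd = 2) {
  session <- match.arg(session)
  if (session == "pre" && learning_effect != 0)
    stop("learning_effect must be 0 for the pre session")
  durations <- c(15, 25, 35, 45, 55, 65)
  rate <- if (session == "pre") subject$heart_rate_pre else subject$heart_rate_post
  coupling <- if (subject$group == "NF") subject$behaviour_coupling else 0
  pf <- min(1, max(0, subject$perception_fraction_pre +
                     coupling * learning_effect * (session == "post")))
  set.seed(as.integer(seed %% 2147483647))
  recorded <- pmax(1, round(rate * durations / 60 +
                              stats::rnorm(6, 0, count_jitter_sd)))
  reported <- pmax(0, round(recorded * pf + stats::rnorm(6, 0, report_noise_sd)))
  confidence <- pmin(100, pmax(0, subject$confidence_pre + stats::rnorm(6, 0, 8)))
  data.frame(duration_seconds = durations, recorded_beats = recorded,
             reported_beats = reported, confidence = confidence)
}
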