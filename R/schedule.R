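#' Acquisition parameters for a neurofeedback session
#'
#' Bundles the scanner timing and region-of-interest (ROI) geometry that every
#' downstream step needs: the repetition time (TR), the number of dummy
#' volumes discarded at run start, the duration of the initial fixation
#' baseline of a regulation run, and the ROI size in voxels.
#'
#' @param tr_seconds Repetition time in seconds (sampling interval of the
#'   volume time series). Default 2.
#' @param n_dummy_volumes Number of initial volumes discarded for T1
#'   equilibration. All volume indices in this package are 0-based and count
#'   from the first retained (post-dummy) volume. Default 3.
#' @param baseline_seconds Duration of the initial fixation baseline of a
#'   regulation run, used as the percent-signal-change reference window.
#'   Must be an integer multiple of `tr_seconds`. Default 20.
#' @param n_voxels Number of voxels in the ROI. Default 150.
#' @return An object of class `acq_params`.
#' @export
acquisition_params <- function(tr_seconds = 2, n_dummy_volumes = 3,
                               baseline_seconds = 20, n_voxels = 150) {
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1 || tr_seconds <= 0)
    stop("tr_seconds must be a single positive number")
  if (n_dummy_volumes < 0) stop("n_dummy_volumes must be >= 0")
  if (baseline_seconds < 0) stop("baseline_seconds must be >= 0")
  if (abs(baseline_seconds / tr_seconds - round(baseline_seconds / tr_seconds)) > 1e-9)
    stop("baseline_seconds must be an integer multiple of tr_seconds")
  if (n_voxels < 1) stop("n_voxels must be >= 1")
  structure(list(tr_seconds = tr_seconds,
                 n_dummy_volumes = as.integer(n_dummy_volumes),
                 baseline_seconds = baseline_seconds,
                 n_voxels = as.integer(n_voxels)),
            class = "acq_params")
}

#' Build the block/trial schedule of a task run
#'
#' Constructs the ordered block timing of either the attention decoder
#' training task or a neurofeedback regulation run.
#'
#' The decoder training task consists of 24 attention trials (12 interoceptive
#' "heart" and 12 exteroceptive "target", strictly alternating), each a
#' 12-second rest period followed by a 10-second attention period (22-second
#' cycle). A regulation run opens with a fixation baseline
#' (`params$baseline_seconds`) followed by 24 alternating blocks of 10-second
#' rest, 10-second regulation, 6-second rating and 4-second feedback
#' (30-second cycle).
#'
#' `n_volumes` is derived from the schedule's total duration (264 volumes for
#' the decoder task and 370 per regulation run at a 2-second TR); pass
#' `n_volumes_override` to emulate an acquisition that stopped early or ran
#' long (the schedule itself is unchanged).
#'
#' @param kind `"decoder_training"` or `"regulation"`.
#' @param params An [acquisition_params()] object.
#' @param run_index Run position in the session: 0 for the decoder training
#'   task, 1-3 for regulation runs.
#' @param first_condition Condition of block 0; alternation is strict so this
#'   fixes the whole sequence. Default `"interoceptive"`.
#' @param n_volumes_override Optional volume count replacing the
#'   schedule-derived one.
#' @param washout_seconds Final fixation appended after the last block so
#'   that haemodynamically delayed feature windows stay inside the run.
#'   Default 4 s for the decoder task (whose last block otherwise ends flush
#'   with the run) and 0 for regulation runs (the rating and feedback
#'   periods already provide the tail).
#' @return An object of class `run_schedule`: a list with elements `kind`,
#'   `run_index`, `blocks` (a data frame with one row per block: `condition`,
#'   `block_index`, `onset_seconds`, `rest_seconds`, `regulation_seconds`,
#'   `rating_seconds`, `feedback_seconds`) and `n_volumes`.
#' @export
build_schedule <- function(kind = c("regulation", "decoder_training"),
                           params = acquisition_params(),
                           run_index = if (kind[1] == "decoder_training") 0L else 1L,
                           first_condition = c("interoceptive", "exteroceptive"),
                           n_volumes_override = NULL,
                           washout_seconds = if (kind[1] == "decoder_training") 4 else 0) {
  kind <- match.arg(kind)
  first_condition <- match.arg(first_condition)
  stopifnot(inherits(params, "acq_params"))
  if (kind == "decoder_training" && run_index != 0)
    stop("decoder training task is run_index 0")
  if (kind == "regulation" && !(run_index %in% 1:3))
    stop("regulation runs are run_index 1, 2 or 3")

  n_blocks <- 24L
  conditions <- rep(c("interoceptive", "exteroceptive"), length.out = n_blocks)
  if (first_condition == "exteroceptive") conditions <- rev(conditions)

  if (kind == "decoder_training") {
    rest <- 12; regulation <- 10; rating <- 0; feedback <- 0; t0 <- 0
  } else {
    rest <- 10; regulation <- 10; rating <- 6; feedback <- 4
    t0 <- params$baseline_seconds
  }
  cycle <- rest + regulation + rating + feedback
  blocks <- data.frame(
    condition = conditions,
    block_index = seq_len(n_blocks) - 1L,
    onset_seconds = t0 + (seq_len(n_blocks) - 1L) * cycle,
    rest_seconds = rest,
    regulation_seconds = regulation,
    rating_seconds = rating,
    feedback_seconds = feedback,
    stringsAsFactors = FALSE
  )
  total_seconds <- t0 + n_blocks * cycle + washout_seconds
  n_volumes <- as.integer(ceiling(total_seconds / params$tr_seconds))
  if (!is.null(n_volumes_override)) n_volumes <- as.integer(n_volumes_override)

  structure(list(kind = kind, run_index = as.integer(run_index),
                 blocks = blocks, n_volumes = n_volumes),
            class = "run_schedule")
}

#' @export
print.run_schedule <- function(x, ...) {
  cat(sprintf("<run_schedule> %s run %d: %d blocks (%d interoceptive), %d volumes\n",
              x$kind, x$run_index, nrow(x$blocks),
              sum(x$blocks$condition == "interoceptive"), x$n_volumes))
  invisible(x)
}

# Onset (seconds from run start) of a block's regulation/attention period.
regulation_onset_seconds <- function(block) {
  block$onset_seconds + block$rest_seconds
}

#' Volume indices of a block's decoder feature window
#'
#' Returns the indices of the last five volumes of a block's regulation
#' (attention) period, shifted forward by `hemodynamic_shift_volumes` to
#' account for the haemodynamic delay. Indices are 0-based, counted from the
#' first post-dummy volume.
#'
#' @param block A single-row slice of a `run_schedule` blocks data frame.
#' @param params An [acquisition_params()] object.
#' @param hemodynamic_shift_volumes Forward shift in volumes; the default 2
#'   (~4 s at a 2-second TR) centres the window on the haemodynamic peak of
#'   the regulation period.
#' @param n_volumes Run length used for the bounds check (optional).
#' @return Integer vector of 5 consecutive 0-based volume indices.
#' @export
regulation_window_volumes <- function(block, params = acquisition_params(),
                                      hemodynamic_shift_volumes = 2L,
                                      n_volumes = NULL) {
  tr <- params$tr_seconds
  on <- regulation_onset_seconds(block)
  off <- on + block$regulation_seconds
  n_in_block <- (off - on) / tr
  if (n_in_block < 5 - 1e-9)
    stop("regulation period spans fewer than 5 volumes at this TR")
  end_vol <- as.integer(round(off / tr)) + as.integer(hemodynamic_shift_volumes)
  idx <- (end_vol - 5L):(end_vol - 1L)
  if (idx[1] < 0) stop("feature window starts before the run")
  if (!is.null(n_volumes) && idx[5] >= n_volumes)
    stop("feature window exceeds run length (", idx[5], " >= ", n_volumes, ")")
  idx
}

#' Event table of a run schedule
#'
#' One row per block giving the onset and duration of its regulation
#' (attention) period in BIDS events style. `trial_type` is `"heart"` for
#' interoceptive and `"target"` for exteroceptive blocks, after the cue words
#' shown to participants.
#'
#' @param schedule A [build_schedule()] object.
#' @return Data frame with columns `onset`, `duration`, `trial_type`,
#'   `block_index`.
#' @export
schedule_events <- function(schedule) {
  stopifnot(inherits(schedule, "run_schedule"))
  b <- schedule$blocks
  data.frame(
    onset = regulation_onset_seconds(b),
    duration = b$regulation_seconds,
    trial_type = ifelse(b$condition == "interoceptive", "heart", "target"),
    block_index = b$block_index,
    stringsAsFactors = FALSE
  )
}
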