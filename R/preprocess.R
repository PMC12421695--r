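#' Baseline volume indices of a run
#'
#' The percent-signal-change reference window: for a regulation run, the
#' initial fixation baseline (`baseline_seconds / tr` volumes); for the
#' decoder training task, which opens directly with a rest period, the first
#' rest period serves as baseline.
#'
#' @param schedule A [build_schedule()] object.
#' @param params An [acquisition_params()] object.
#' @return 0-based volume indices of the baseline window.
#' @export
baseline_window <- function(schedule, params = acquisition_params()) {
  tr <- params$tr_seconds
  secs <- if (schedule$kind == "regulation") params$baseline_seconds
          else schedule$blocks$rest_seconds[1]
  n <- as.integer(round(secs / tr))
  if (n < 1) stop("baseline window is empty")
  0:(n - 1L)
}

#' Percent signal change relative to the run baseline
#'
#' Expresses each voxel's time course as percent deviation from its own mean
#' over the baseline window: `psc[t, v] = 100 * (raw[t, v] - m_v) / m_v`
#' where `m_v` is voxel `v`'s mean over the baseline volumes.
#'
#' @param raw Either a `roi_timeseries` object (see [simulate_run()]) or a
#'   volumes x voxels numeric matrix.
#' @param baseline_volumes 0-based volume indices of the baseline window;
#'   derived from the schedule via [baseline_window()] when `raw` is a
#'   `roi_timeseries`.
#' @return A volumes x voxels matrix in percent units.
#' @export
percent_signal_change <- function(raw, baseline_volumes = NULL) {
  if (inherits(raw, "roi_timeseries")) {
    if (is.null(baseline_volumes))
      baseline_volumes <- baseline_window(raw$schedule, raw$params)
    raw <- raw$data
  }
  if (is.null(baseline_volumes)) stop("baseline_volumes required for a bare matrix")
  if (!is.matrix(raw)) stop("raw must be a matrix")
  if (any(baseline_volumes < 0) || any(baseline_volumes >= nrow(raw)))
    stop("baseline window out of bounds")
  m <- colMeans(raw[baseline_volumes + 1L, , drop = FALSE])
  bad <- which(m == 0)
  if (length(bad))
    stop("zero baseline mean in voxel(s): ", paste(bad, collapse = ", "))
  100 * (raw %*% diag(1 / m, length(m)) - 1)
}

#' Spatiotemporal trial features for the decoder
#'
#' Extracts, for each block, the percent-signal-change values of the last
#' five volumes of its regulation period (shifted for haemodynamic delay)
#' across all ROI voxels, flattened volume-major (all voxels of the first
#' window volume, then all voxels of the second, ...). Features are NOT
#' normalised or centred: amplitude information is preserved, and the
#' flattening order is fixed so that training and feedback paths see
#' bit-identical layouts.
#'
#' @param psc Volumes x voxels percent-signal-change matrix.
#' @param schedule A [build_schedule()] object.
#' @param params An [acquisition_params()] object.
#' @param shift Haemodynamic shift in volumes (see
#'   [regulation_window_volumes()]). Default 2.
#' @return A `trial_features` object: list with `features` (trials x
#'   `5 * n_voxels` matrix), `labels` (condition per trial) and `run_index`.
#' @export
extract_trial_features <- function(psc, schedule, params = acquisition_params(),
                                   shift = 2L) {
  stopifnot(is.matrix(psc), inherits(schedule, "run_schedule"))
  b <- schedule$blocks
  feats <- matrix(NA_real_, nrow = nrow(b), ncol = 5L * ncol(psc))
  for (i in seq_len(nrow(b))) {
    idx <- regulation_window_volumes(b[i, ], params, shift, n_volumes = nrow(psc))
    feats[i, ] <- as.vector(t(psc[idx + 1L, , drop = FALSE]))
  }
  if (any(!is.finite(feats))) stop("non-finite feature values")
  structure(list(features = feats, labels = b$condition,
                 run_index = schedule$run_index),
            class = "trial_features")
}
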