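#' Canonical double-gamma haemodynamic response function
#'
#' The canonical HRF: a gamma density peaking at 6 s minus a 16-s-peak
#' undershoot gamma at 1/6 amplitude (unit dispersions), evaluated over 32 s
#' at the TR and normalised to a peak of 1.
#'
#' @param tr_seconds Sampling interval (TR) in seconds.
#' @param duration_seconds Kernel length. Default 32.
#' @return Numeric vector of kernel samples at `0, tr, 2 tr, ...`.
#' @export
canonical_hrf <- function(tr_seconds, duration_seconds = 32) {
  stopifnot(tr_seconds > 0)
  t <- seq(0, duration_seconds, by = tr_seconds)
  h <- stats::dgamma(t, shape = 6, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
  h / max(h)
}

# HRF-convolved regressor: unit boxcars at the given [onset, offset) windows
# (seconds), sampled at volume acquisition times, convolved with the
# canonical kernel and truncated to the run.
hrf_regressor <- function(onsets, offsets, n_volumes, tr_seconds) {
  box <- numeric(n_volumes)
  t <- (seq_len(n_volumes) - 1L) * tr_seconds
  for (i in seq_along(onsets))
    box[t >= onsets[i] & t < offsets[i]] <- 1
  kern <- canonical_hrf(tr_seconds)
  out <- stats::convolve(box, rev(kern), type = "open")[seq_len(n_volumes)]
  out
}

#' Trial-wise beta-series design matrix
#'
#' Least-squares-all design for single-trial response estimation: one
#' regressor per trial (a 10-second boxcar over that trial's regulation
#' period convolved with the canonical HRF), plus an intercept and a linear
#' drift column. Rest, rating and feedback periods are left unmodelled and
#' form the implicit baseline. Optional motion parameters are appended as
#' nuisance columns.
#'
#' @param schedule A [build_schedule()] object.
#' @param params An [acquisition_params()] object.
#' @param n_volumes Run length in volumes. Defaults to the schedule's.
#' @param motion Optional volumes x 6 matrix of motion parameters.
#' @return List with `matrix` (volumes x regressors), `trial_columns`
#'   (indices of the 24 trial regressors) and `labels` (condition per trial).
#' @export
build_beta_series_design <- function(schedule, params = acquisition_params(),
                                     n_volumes = schedule$n_volumes,
                                     motion = NULL) {
  b <- schedule$blocks
  tr <- params$tr_seconds
  n_trials <- nrow(b)
  X <- matrix(0, n_volumes, n_trials)
  for (i in seq_len(n_trials)) {
    on <- regulation_onset_seconds(b[i, ])
    X[, i] <- hrf_regressor(on, on + b$regulation_seconds[i], n_volumes, tr)
  }
  colnames(X) <- sprintf("trial_%02d", b$block_index)
  nuis <- cbind(intercept = rep(1, n_volumes),
                drift = seq(-1, 1, length.out = n_volumes))
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    stopifnot(nrow(motion) == n_volumes)
    colnames(motion) <- sprintf("motion_%d", seq_len(ncol(motion)))
    nuis <- cbind(nuis, motion)
  }
  X <- cbind(X, nuis)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient beta-series design")
  list(matrix = X, trial_columns = seq_len(n_trials), labels = b$condition)
}

#' Estimate single-trial betas by ordinary least squares
#'
#' Per-voxel OLS fit of the beta-series design; returns the trial
#' coefficients only (nuisance coefficients are discarded).
#'
#' @param psc Volumes x voxels data matrix (percent signal change).
#' @param design A [build_beta_series_design()] object.
#' @param run_index Run index stored with the result.
#' @return A `beta_series` object: `betas` (trials x voxels), `labels`,
#'   `run_index`.
#' @export
estimate_trial_betas <- function(psc, design, run_index = NA_integer_) {
  X <- design$matrix
  stopifnot(is.matrix(psc), nrow(psc) == nrow(X))
  coefs <- qr.coef(qr(X), psc)
  betas <- coefs[design$trial_columns, , drop = FALSE]
  if (any(!is.finite(betas))) stop("non-finite betas (rank-deficient design?)")
  structure(list(betas = unname(betas), labels = design$labels,
                 run_index = run_index),
            class = "beta_series")
}

#' Two-fold cross-validated pattern classification accuracy
#'
#' Splits a run's trials into two class-balanced folds by alternating trial
#' order within each condition (trials 1st, 3rd, 5th ... of a condition in
#' fold 1; 2nd, 4th, ... in fold 2), trains the linear SVM (C = 1) on one
#' fold, tests on the other, and averages the two directions. The fold
#' assignment is deterministic, so `seed` is accepted for interface
#' compatibility but has no effect.
#'
#' @param betas A `beta_series` object, or a trials x voxels matrix (then
#'   `labels` is required).
#' @param labels Condition labels, one per trial (when `betas` is a matrix).
#' @param c_param SVM regularisation parameter. Default 1.
#' @param seed Ignored (deterministic folds); present for API stability.
#' @return Classification accuracy in `[0, 1]`.
#' @export
two_fold_cv_accuracy <- function(betas, labels = NULL, c_param = 1, seed = NULL) {
  if (inherits(betas, "beta_series")) {
    labels <- betas$labels
    betas <- betas$betas
  }
  stopifnot(is.matrix(betas), length(labels) == nrow(betas))
  y <- ifelse(labels == "interoceptive", 1L, -1L)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (sum(y == 1) != sum(y == -1)) stop("labels must be balanced")

  fold <- integer(length(y))
  for (cls in c(1L, -1L)) {
    idx <- which(y == cls)
    fold[idx] <- rep(c(1L, 2L), length.out = length(idx))
  }
  acc <- vapply(1:2, function(test_fold) {
    train <- fold != test_fold
    fit <- train_linear_svm(betas[train, , drop = FALSE], y[train],
                            c_param = c_param)
    pred <- sign(decision_value(fit, betas[!train, , drop = FALSE]))
    pred[pred == 0] <- -1L  # on-boundary prediction counts as exteroceptive
    mean(pred == y[!train])
  }, numeric(1))
  mean(acc)
}
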