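#' Train the linear soft-margin SVM decoder
#'
#' Fits the standard linear soft-margin support vector machine
#' (`min 1/2 ||w||^2 + C * sum hinge`) via LIBSVM (through \pkg{e1071}),
#' the solver used for real-time attention-state decoding. Features are used
#' as-is (no scaling). Label `+1` codes the interoceptive class and positive
#' decision values favour it.
#'
#' @param x Trials x features numeric matrix.
#' @param y Labels, one per row of `x`, coded +1 (interoceptive) / -1
#'   (exteroceptive).
#' @param c_param Regularisation parameter C. Default 1.
#' @param tolerance Termination tolerance of the LIBSVM optimiser. The tight
#'   default makes the solution comparable to an exact quadratic-program
#'   solution on small instances.
#' @return List with `weights` (length = feature count) and `bias`.
#' @export
train_linear_svm <- function(x, y, c_param = 1, tolerance = 1e-8) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (c_param <= 0) stop("c_param must be positive")
  y <- as.integer(sign(y))
  if (length(unique(y)) < 2) stop("both classes must be present")
  yf <- factor(y, levels = c(1L, -1L))
  fit <- e1071::svm(x, yf, type = "C-classification", kernel = "linear",
                    cost = c_param, scale = FALSE, tolerance = tolerance)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # e1071 orients decision values towards the first factor level (+1 here);
  # guard against the rare inverted labelling of the internal solver.
  dv <- drop(x %*% w + b)
  ori <- suppressWarnings(stats::cor(dv, y))
  if (!is.na(ori) && ori < 0) { w <- -w; b <- -b }
  list(weights = unname(w), bias = unname(b))
}

#' Decoder decision value
#'
#' `f(x) = w . x + b`, the signed distance (up to `||w||`) from the decision
#' boundary; positive values favour the interoceptive state.
#'
#' @param model A list with `weights` and `bias` ([train_linear_svm()] or
#'   [train_run_decoder()] output).
#' @param feature Numeric vector (one trial), a trials x features matrix, or
#'   a `trial_features` object.
#' @return Numeric vector of decision values.
#' @export
decision_value <- function(model, feature) {
  if (inherits(feature, "trial_features")) feature <- feature$features
  if (!is.matrix(feature)) feature <- matrix(feature, nrow = 1)
  if (ncol(feature) != length(model$weights))
    stop("feature length ", ncol(feature), " does not match decoder (",
         length(model$weights), ")")
  drop(feature %*% model$weights + model$bias)
}

#' Fit Platt probability calibration
#'
#' Maximum-likelihood fit of the logistic map
#' `P(y = 1 | x) = 1 / (1 + exp(A * f(x) + B))` from decision values to class
#' probabilities, using Platt's regularised targets
#' `(N+ + 1)/(N+ + 2)` and `1/(N- + 2)` so the fit stays finite on
#' perfectly separated data. The orientation constraint `A <= 0` guarantees
#' that larger decision values give larger interoceptive probability.
#'
#' The optimiser is the standard damped Newton iteration on the two-parameter
#' negative log-likelihood.
#'
#' @param decisions Numeric vector of decoder decision values.
#' @param labels +1/-1 class labels, one per decision.
#' @param max_iter,tol Newton iteration controls.
#' @return Named vector `c(A, B)`.
#' @export
fit_platt <- function(decisions, labels, max_iter = 200L, tol = 1e-12) {
  stopifnot(length(decisions) == length(labels))
  labels <- as.integer(sign(labels))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == -1)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  t_i <- ifelse(labels == 1, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  f <- as.numeric(decisions)

  nll <- function(ab) {
    z <- ab[1] * f + ab[2]
    # -sum(t*log(p) + (1-t)*log(1-p)) with p = 1/(1+exp(z)), stable form
    sum(ifelse(z >= 0, t_i * z + log1p(exp(-z)), (t_i - 1) * z + log1p(exp(z))))
  }
  ab <- c(A = 0, B = log((n_neg + 1) / (n_pos + 1)))
  sigma <- 1e-12  # Hessian ridge
  val <- nll(ab)
  for (it in seq_len(max_iter)) {
    z <- ab[1] * f + ab[2]
    p <- 1 / (1 + exp(z))
    d1 <- p * (1 - p)
    g <- c(sum(f * (t_i - p)), sum(t_i - p))          # gradient of nll
    h11 <- sum(f * f * d1) + sigma
    h12 <- sum(f * d1)
    h22 <- sum(d1) + sigma
    det <- h11 * h22 - h12 * h12
    step <- c(h22 * g[1] - h12 * g[2], -h12 * g[1] + h11 * g[2]) / det
    if (max(abs(g)) < tol) break
    # backtracking line search
    stepsize <- 1
    repeat {
      ab_new <- ab - stepsize * step
      val_new <- nll(ab_new)
      if (val_new < val + 1e-4 * stepsize * sum(-step * g) + 1e-15) break
      stepsize <- stepsize / 2
      if (stepsize < 1e-10) { ab_new <- ab; val_new <- val; break }
    }
    if (max(abs(ab_new - ab)) < tol) { ab <- ab_new; break }
    ab <- ab_new; val <- val_new
  }
  if (ab[1] > 0) {
    # degenerate orientation: clamp the slope, refit the intercept alone
    tbar <- mean(t_i)
    ab <- c(0, log((1 - tbar) / tbar))
  }
  stats::setNames(as.numeric(ab), c("A", "B"))
}

#' Platt-calibrated interoceptive probability
#'
#' @param model A decoder model with `platt_a`, `platt_b`.
#' @param decision Decision value(s) from [decision_value()].
#' @return Probability of the interoceptive state, in `[0, 1]`.
#' @export
platt_probability <- function(model, decision) {
  1 / (1 + exp(model$platt_a * decision + model$platt_b))
}

#' Assemble the incremental training set for a regulation run
#'
#' The decoder for regulation run 1 is trained exclusively on the attention
#' decoder training task; for runs 2 and 3 it is incrementally retrained on
#' the decoder task plus all preceding regulation runs, in chronological
#' order.
#'
#' @param history List of `trial_features` objects, one per completed run,
#'   with `run_index` 0 (decoder task) up to `target_run - 1`.
#' @param target_run Regulation run to train for (1, 2 or 3).
#' @return List with `features` (stacked matrix), `labels` (+1/-1) and
#'   `runs` (source run index per trial).
#' @export
assemble_training_set <- function(history, target_run) {
  if (!target_run %in% 1:3) stop("target_run must be 1, 2 or 3")
  idx <- vapply(history, function(h) h$run_index, integer(1))
  need <- 0:(target_run - 1L)
  if (!all(need %in% idx))
    stop("missing history for run(s): ",
         paste(setdiff(need, idx), collapse = ", "))
  parts <- lapply(need, function(r) history[[which(idx == r)[1]]])
  feats <- do.call(rbind, lapply(parts, function(h) h$features))
  labs <- unlist(lapply(parts, function(h)
    ifelse(h$labels == "interoceptive", 1L, -1L)))
  runs <- unlist(lapply(parts, function(h) rep(h$run_index, nrow(h$features))))
  list(features = feats, labels = labs, runs = runs)
}

#' Train the calibrated decoder for a regulation run
#'
#' Composite of [assemble_training_set()], [train_linear_svm()],
#' [decision_value()] on the training set, and [fit_platt()]: the SVM and the
#' Platt calibration are fitted on the same pooled data, and both are
#' re-estimated at every run as new regulation data accrue, keeping the
#' probability transformation calibrated across runs.
#'
#' @inheritParams assemble_training_set
#' @param c_param SVM regularisation parameter. Default 1.
#' @return A `decoder_model` object: `weights`, `bias`, `c_param`, `platt_a`,
#'   `platt_b`, `trained_on_runs`.
#' @export
train_run_decoder <- function(history, target_run, c_param = 1) {
  ts <- assemble_training_set(history, target_run)
  svm_fit <- train_linear_svm(ts$features, ts$labels, c_param = c_param)
  dv <- decision_value(svm_fit, ts$features)
  platt <- fit_platt(dv, ts$labels)
  structure(list(weights = svm_fit$weights, bias = svm_fit$bias,
                 c_param = c_param,
                 platt_a = platt[["A"]], platt_b = platt[["B"]],
                 trained_on_runs = sort(unique(ts$runs))),
            class = "decoder_model")
}

#' @export
print.decoder_model <- function(x, ...) {
  cat(sprintf("<decoder_model> %d features, C = %g, Platt (A, B) = (%.4f, %.4f), trained on runs %s\n",
              length(x$weights), x$c_param, x$platt_a, x$platt_b,
              paste(x$trained_on_runs, collapse = ", ")))
  invisible(x)
}
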