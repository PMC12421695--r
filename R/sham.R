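#' Fit the sham (yoked) feedback model from neurofeedback-group scores
#'
#' Estimates the statistical structure of real displayed feedback so that
#' non-contingent sham scores can be generated from it: the unconditional
#' score distribution over fixed-width score bins, the first-order transition
#' table between bins (from consecutive within-run trial pairs), per-bin
#' pools of observed scores (sampling from the pools preserves the empirical
#' within-bin shape), and run-specific success rates. The success rates
#' default to the correct-classification rates observed in the original
#' neurofeedback group (48.512, 58.589, 62.500 percent for runs 1-3) and can
#' instead be re-estimated from the supplied scores.
#'
#' @param nf_scores_by_run List of length 3 (runs 1-3). Each element is
#'   either a numeric vector of displayed scores in trial order, or a list of
#'   such vectors (one per subject); transitions are only counted within a
#'   subject's run.
#' @param bin_width Width of the score bins on `[0, 100]`. Default 10.
#' @param run_success_rates Percentage of successful (> 50) trials per run
#'   used when generating sham sessions.
#' @param estimate_rates If `TRUE`, replace `run_success_rates` by the
#'   fraction of supplied scores > 50 per run.
#' @param condition_on How the transition table is conditioned: on the
#'   previous trial's score bin (`"bins"`, default) or only on its
#'   success/failure outcome (`"outcome"`).
#' @return An object of class `sham_model`.
#' @export
fit_sham_model <- function(nf_scores_by_run, bin_width = 10,
                           run_success_rates = c(48.512, 58.589, 62.500),
                           estimate_rates = FALSE,
                           condition_on = c("bins", "outcome")) {
  condition_on <- match.arg(condition_on)
  if (length(nf_scores_by_run) != 3) stop("expected scores for 3 regulation runs")
  seqs <- lapply(nf_scores_by_run, function(r) {
    if (is.list(r)) lapply(r, as.numeric) else list(as.numeric(r))
  })
  all_scores <- unlist(seqs)
  if (length(all_scores) == 0) stop("empty score input")
  if (any(all_scores < 0 | all_scores > 100)) stop("scores outside [0, 100]")

  breaks <- seq(0, 100, by = bin_width)
  if (breaks[length(breaks)] < 100) breaks <- c(breaks, 100)
  n_bins <- length(breaks) - 1L
  bin_of <- function(s) pmin(findInterval(s, breaks, rightmost.closed = TRUE), n_bins)

  bins <- bin_of(all_scores)
  unconditional <- tabulate(bins, nbins = n_bins) / length(all_scores)
  pools <- lapply(seq_len(n_bins), function(b) all_scores[bins == b])

  if (condition_on == "bins") {
    transition <- matrix(0, n_bins, n_bins)
    for (run in seqs) for (s in run) {
      if (length(s) >= 2) {
        b <- bin_of(s)
        for (i in seq_len(length(s) - 1))
          transition[b[i], b[i + 1]] <- transition[b[i], b[i + 1]] + 1
      }
    }
  } else {
    # two "bins of origin": failure (<= 50) and success (> 50); the table is
    # expanded onto score bins via the destination's bin
    transition <- matrix(0, 2, n_bins)
    for (run in seqs) for (s in run) {
      if (length(s) >= 2) {
        from <- ifelse(s > 50, 2L, 1L)
        to <- bin_of(s)
        for (i in seq_len(length(s) - 1))
          transition[from[i], to[i + 1]] <- transition[from[i], to[i + 1]] + 1
      }
    }
  }
  row_n <- rowSums(transition)
  transition_p <- transition
  nonzero <- row_n > 0
  transition_p[nonzero, ] <- transition[nonzero, , drop = FALSE] / row_n[nonzero]

  if (estimate_rates)
    run_success_rates <- vapply(seqs, function(run)
      100 * mean(unlist(run) > 50), numeric(1))
  stopifnot(all(run_success_rates >= 0 & run_success_rates <= 100))

  model <- structure(list(bin_width = bin_width, breaks = breaks,
                          unconditional = unconditional, pools = pools,
                          transition = transition_p, transition_n = row_n,
                          run_success_rates = run_success_rates,
                          condition_on = condition_on),
                     class = "sham_model")
  model$cache <- build_sham_cache(model)
  model
}

# Precomputed success/failure-restricted distributions and pools, so that
# per-trial sampling is two table lookups.
build_sham_cache <- function(model) {
  lapply(c(failure = FALSE, success = TRUE), function(success) {
    pools <- lapply(model$pools, function(p)
      if (success) p[p > 50] else p[p <= 50])
    trans <- t(apply(model$transition, 1, function(row) {
      w <- restrict_bins(model, row, success)
      if (is.null(w)) rep(NA_real_, length(row)) else w
    }))
    list(uncond = restrict_bins(model, model$unconditional, success),
         trans = trans, pools = pools)
  })
}

#' @export
print.sham_model <- function(x, ...) {
  cat(sprintf("<sham_model> %d score bins (width %g), success rates %s%%, conditioning on %s\n",
              length(x$unconditional), x$bin_width,
              paste(sprintf("%.3f", x$run_success_rates), collapse = "/"),
              x$condition_on))
  invisible(x)
}

# Restrict a bin distribution to the success (> 50) or failure (<= 50) score
# range, weighting each bin by the fraction of its pool inside the range.
# Returns NULL when the restricted distribution carries no mass.
restrict_bins <- function(model, bin_probs, success) {
  frac <- vapply(model$pools, function(p) {
    if (length(p) == 0) return(0)
    mean(if (success) p > 50 else p <= 50)
  }, numeric(1))
  w <- bin_probs * frac
  if (sum(w) <= 0) return(NULL)
  w / sum(w)
}

#' Sample one sham feedback score
#'
#' A trial's success or failure is first drawn from the run-specific success
#' rate. The score is then sampled from the transition row of the previous
#' score's bin (or from the unconditional distribution for the first trial or
#' when the row was never observed), restricted to the success (`> 50`) or
#' failure (`<= 50`) score range, with the actual value drawn from the
#' matching empirical within-bin pool. Uses R's global random number stream.
#'
#' @param model A [fit_sham_model()] object.
#' @param run_index Regulation run (1, 2 or 3) whose success rate applies.
#' @param prev_score Previous displayed score, or `NULL` for the first trial.
#' @return A single score.
#' @export
sample_sham_trial <- function(model, run_index, prev_score = NULL) {
  sample_sham_scores(model, run_index, 1L, prev_score)
}

#' Sample a chained sequence of sham scores
#'
#' Vectorised form of [sample_sham_trial()]: draws `n` consecutive trials of
#' one run, each conditioned on its predecessor (the first on `prev_score`,
#' or unconditionally when `NULL`).
#'
#' @inheritParams sample_sham_trial
#' @param n Number of trials.
#' @return Numeric vector of `n` scores.
#' @export
sample_sham_scores <- function(model, run_index, n, prev_score = NULL) {
  stopifnot(run_index %in% 1:3, n >= 1)
  if (is.null(model$cache)) model$cache <- build_sham_cache(model)
  n_bins <- length(model$unconditional)
  by_outcome <- model$condition_on == "outcome"

  # cumulative bin distributions; NA marks an unobserved/empty row
  cum <- lapply(model$cache, function(cc) list(
    uncond = if (is.null(cc$uncond)) NULL else cumsum(cc$uncond),
    trans = t(apply(cc$trans, 1, cumsum)),
    pools = cc$pools))
  ok_row <- cbind(failure = !is.na(cum$failure$trans[, n_bins]) & model$transition_n > 0,
                  success = !is.na(cum$success$trans[, n_bins]) & model$transition_n > 0)

  u_succ <- stats::runif(n) < model$run_success_rates[run_index] / 100
  u_bin <- stats::runif(n)
  u_val <- stats::runif(n)
  out <- numeric(n)
  prev <- prev_score
  for (i in seq_len(n)) {
    k <- if (u_succ[i]) 2L else 1L
    cc <- cum[[k]]
    probs <- NULL
    if (!is.null(prev)) {
      from <- if (by_outcome) {
        if (prev > 50) 2L else 1L
      } else min(findInterval(prev, model$breaks, rightmost.closed = TRUE), n_bins)
      if (ok_row[from, k]) probs <- cc$trans[from, ]
    }
    if (is.null(probs)) probs <- cc$uncond
    if (is.null(probs))
      stop("sham model has no observed scores in the required range")
    bin <- which(u_bin[i] <= probs / probs[length(probs)])[1]
    pool <- cc$pools[[bin]]
    out[i] <- pool[max(1L, ceiling(u_val[i] * length(pool)))]
    prev <- out[i]
  }
  out
}

#' Generate a full sham feedback session
#'
#' Three regulation runs of 24 displayed scores each. The first trial of the
#' session is sampled unconditionally; every later trial is chained through
#' the transition structure via [sample_sham_trial()]. The sequence is a
#' deterministic function of R's random number stream (seed it with
#' `set.seed()` for reproducibility) and is entirely independent of any
#' subject's brain data.
#'
#' @param model A [fit_sham_model()] object.
#' @param n_runs,n_trials Session shape. Defaults 3 x 24.
#' @return `n_runs` x `n_trials` matrix of scores.
#' @export
generate_sham_session <- function(model, n_runs = 3L, n_trials = 24L) {
  scores <- matrix(NA_real_, n_runs, n_trials)
  prev <- NULL
  for (r in seq_len(n_runs)) {
    scores[r, ] <- sample_sham_scores(model, min(r, 3L), n_trials, prev)
    prev <- scores[r, n_trials]
  }
  scores
}
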