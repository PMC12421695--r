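#' Interoceptive accuracy from a heartbeat counting session
#'
#' Mean over trials of `1 - |recorded - reported| / recorded`. Scores above
#' ~1 are impossible only for under-reporting; systematic over-reporting can
#' drive single-trial values negative, and the score is deliberately not
#' clamped.
#'
#' @param trials Data frame with columns `recorded_beats` and
#'   `reported_beats` (and typically `duration_seconds`, `confidence`), one
#'   row per trial.
#' @return The accuracy score (1 = perfect counting).
#' @export
interoceptive_accuracy <- function(trials) {
  rec <- trials$recorded_beats
  rep_ <- trials$reported_beats
  if (any(rec <= 0)) stop("recorded_beats must be positive")
  mean(1 - abs(rec - rep_) / rec)
}

#' Actual and perceived heart rate of a session
#'
#' Converts each trial's counts to beats per minute and averages across
#' trials.
#'
#' @param trials Heartbeat trial data frame (see [interoceptive_accuracy()])
#'   with a `duration_seconds` column.
#' @return Named vector `c(actual_bpm, perceived_bpm)`.
#' @export
bpm_summary <- function(trials) {
  if (any(trials$duration_seconds <= 0)) stop("durations must be positive")
  c(actual_bpm = mean(60 * trials$recorded_beats / trials$duration_seconds),
    perceived_bpm = mean(60 * trials$reported_beats / trials$duration_seconds))
}

#' One-sample t test (direct implementation)
#'
#' Tests whether the mean of `x` differs from zero; reports the mean, t, df,
#' two-sided p, Cohen's d (`mean / sd`) and a 95 percent confidence interval
#' for the mean.
#'
#' @param x Numeric vector.
#' @return Named list.
#' @export
one_sample_t <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least 2 observations")
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) {
    return(list(mean = m, sd = s, n = n, t = if (m == 0) 0 else Inf * sign(m),
                df = n - 1, p = if (m == 0) 1 else 0, d = if (m == 0) 0 else Inf * sign(m),
                ci = c(m, m)))
  }
  se <- s / sqrt(n)
  t_stat <- m / se
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  half <- stats::qt(0.975, df = n - 1) * se
  list(mean = m, sd = s, n = n, t = t_stat, df = n - 1, p = p, d = m / s,
       ci = c(m - half, m + half))
}

#' Pearson correlation with Fisher confidence interval
#'
#' Direct implementation: `r`, its t statistic with `n - 2` df, two-sided p,
#' and the 95 percent confidence interval from the Fisher z transform.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Named list.
#' @export
pearson_ci <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  xc <- x - mean(x); yc <- y - mean(y)
  denom <- sqrt(sum(xc^2) * sum(yc^2))
  if (denom == 0) stop("degenerate variance in correlation input")
  r <- sum(xc * yc) / denom
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  z <- atanh(r); se <- 1 / sqrt(n - 3)
  ci <- tanh(c(z - 1.96 * se, z + 1.96 * se))
  list(r = r, n = n, t = t_stat, df = n - 2, p = p, ci = ci)
}

#' Compare two independent correlations (Fisher r-to-z)
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' one-tailed p (`r1 > r2`) by default.
#'
#' @param r1,n1 First correlation and its sample size.
#' @param r2,n2 Second correlation and its sample size.
#' @param alternative `"greater"` (one-tailed, default) or `"two.sided"`.
#' @return Named list with `z` and `p`.
#' @export
fisher_rz_compare <- function(r1, n1, r2, n2,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(n1 > 3, n2 > 3)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- if (alternative == "greater") stats::pnorm(-z) else 2 * stats::pnorm(-abs(z))
  list(z = z, p = p)
}

#' Group-level behavioural/regulation statistics
#'
#' For each group: one-sample t tests on the score and classification-
#' accuracy learning effects, and the Pearson correlation between each
#' learning-effect index and the change in interoceptive accuracy; plus the
#' between-group Fisher r-to-z comparison of the accuracy-learning
#' correlation. Also emits per-cell descriptives (pre/post accuracy and heart
#' rates) for external repeated-measures analyses.
#'
#' @param outcomes Data frame with one row per subject and columns `group`
#'   (`"NF"`/`"Sham"`), `le_score`, `le_ca`, `ia_pre`, `ia_post`,
#'   `delta_ia`, `bpm_actual_pre`, `bpm_actual_post`, `bpm_perceived_pre`,
#'   `bpm_perceived_post`.
#' @return Nested list report (per group: `t_le_score`, `t_le_ca`,
#'   `cor_score`, `cor_ca`, `descriptives`; plus `rz_ca`, `rz_score`).
#' @export
group_statistics <- function(outcomes) {
  per_group <- function(g) {
    o <- outcomes[outcomes$group == g, ]
    if (nrow(o) < 3) stop("need at least 3 subjects per group")
    list(
      n = nrow(o),
      t_le_score = one_sample_t(o$le_score),
      t_le_ca = one_sample_t(o$le_ca),
      cor_score = pearson_ci(o$le_score, o$delta_ia),
      cor_ca = pearson_ci(o$le_ca, o$delta_ia),
      descriptives = colMeans(o[, c("ia_pre", "ia_post", "delta_ia",
                                    "bpm_actual_pre", "bpm_actual_post",
                                    "bpm_perceived_pre", "bpm_perceived_post")])
    )
  }
  nf <- per_group("NF"); sham <- per_group("Sham")
  list(NF = nf, Sham = sham,
       rz_ca = fisher_rz_compare(nf$cor_ca$r, nf$n, sham$cor_ca$r, sham$n),
       rz_score = fisher_rz_compare(nf$cor_score$r, nf$n, sham$cor_score$r, sham$n))
}
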