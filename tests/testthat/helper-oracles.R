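# Independent oracles used across the suite. These deliberately share no
# code with the package implementation.

# Soft-margin linear SVM solved in the dual by plain pairwise SMO sweeps,
# run to tight KKT precision. Suitable for small instances only.
oracle_svm <- function(X, y, C = 1, tol = 1e-12, max_sweeps = 5000) {
  n <- nrow(X)
  K <- X %*% t(X)
  alpha <- rep(0, n)
  f <- rep(0, n)  # K %*% (alpha * y), maintained incrementally
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      eta <- K[i, i] + K[j, j] - 2 * K[i, j]
      if (eta <= 0) next
      e_i <- f[i] - y[i]; e_j <- f[j] - y[j]
      if (y[i] == y[j]) {
        lo <- max(0, alpha[i] + alpha[j] - C); hi <- min(C, alpha[i] + alpha[j])
      } else {
        lo <- max(0, alpha[j] - alpha[i]); hi <- min(C, C + alpha[j] - alpha[i])
      }
      if (lo >= hi) next
      aj <- alpha[j] + y[j] * (e_i - e_j) / eta
      aj <- min(hi, max(lo, aj))
      ai <- alpha[i] + y[i] * y[j] * (alpha[j] - aj)
      delta <- max(delta, abs(aj - alpha[j]))
      f <- f + K[, i] * (y[i] * (ai - alpha[i])) + K[, j] * (y[j] * (aj - alpha[j]))
      alpha[j] <- aj; alpha[i] <- ai
    }
    if (delta < tol) break
  }
  w <- as.vector(t(X) %*% (alpha * y))
  fx <- as.vector(X %*% w)
  free <- alpha > 1e-8 & alpha < C - 1e-8
  b <- if (any(free)) mean(y[free] - fx[free]) else {
    # all alphas at bounds: b lies in an interval; take its midpoint
    up <- min(c((y - fx)[(y == 1 & alpha < C - 1e-8) | (y == -1 & alpha > 1e-8)], Inf))
    lo <- max(c((y - fx)[(y == -1 & alpha < C - 1e-8) | (y == 1 & alpha > 1e-8)], -Inf))
    mean(c(lo, up)[is.finite(c(lo, up))])
  }
  list(weights = w, bias = b, alpha = alpha)
}

# Primal soft-margin objective for any (w, b).
svm_primal_objective <- function(w, b, X, y, C = 1) {
  margins <- 1 - y * (as.vector(X %*% w) + b)
  0.5 * sum(w^2) + C * sum(pmax(0, margins))
}

# Platt calibration fitted by general-purpose optimisation over the
# regularised-target likelihood (oracle for the package's Newton fit).
oracle_platt <- function(decisions, labels) {
  n_pos <- sum(labels == 1); n_neg <- sum(labels == -1)
  t_i <- ifelse(labels == 1, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  nll <- function(ab) {
    z <- ab[1] * decisions + ab[2]
    sum(ifelse(z >= 0, t_i * z + log1p(exp(-z)), (t_i - 1) * z + log1p(exp(z))))
  }
  fit <- optim(c(0, 0), nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  fit$par
}

# A small, well-separated decoder problem with known structure.
toy_features <- function(n_per_class = 12, d = 6, sep = 4, sd = 0.5,
                         seed = 11) {
  set.seed(seed)
  centre <- c(rep(sep / 2, d %/% 2), rep(0, d - d %/% 2))
  x <- rbind(matrix(rnorm(n_per_class * d, sd = sd), ncol = d) +
               rep(centre, each = n_per_class),
             matrix(rnorm(n_per_class * d, sd = sd), ncol = d) -
               rep(centre, each = n_per_class))
  list(x = x, y = rep(c(1, -1), each = n_per_class))
}

# Tiny cohort configuration used where run content does not matter much.
tiny_config <- function(...) {
  cohort_config(n_nf = 2L, n_sham = 2L,
                params = acquisition_params(n_voxels = 20L), ...)
}
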