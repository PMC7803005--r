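# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: plain normal equations, a literal pure-R IRLS
# transcription of the fitting recipe, exhaustive active-set enumeration for
# NNLS, and the textbook covariance formula for Pearson correlation.

ols_oracle <- function(y, X) {
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# Pure-R Huber IRLS: OLS start; zero-centred MAD scale; w = min(1, ks/|r|);
# weighted LS via normal equations; relative coefficient convergence.
huber_irls_oracle <- function(y, X, k = 1.345, max_iter = 50, tol = 1e-6,
                              scale_floor = 0) {
  beta <- ols_oracle(y, X)
  for (it in seq_len(max_iter)) {
    r <- y - as.numeric(X %*% beta)
    s <- median(abs(r)) / 0.6745
    if (s <= scale_floor) return(list(coefficients = beta, scale = s))
    w <- pmin(1, k * s / abs(r))
    W <- diag(w, length(y))
    beta_new <- as.numeric(solve(t(X) %*% W %*% X, t(X) %*% W %*% y))
    delta <- max(abs(beta_new - beta) / pmax(1, abs(beta)))
    beta <- beta_new
    if (delta < tol) break
  }
  list(coefficients = beta, scale = s)
}

# Exact NNLS by exhaustive enumeration of active sets (feasible for <= 3
# predictors): for every subset of free coefficients, take the unconstrained
# LS solution on that subset (others pinned at 0); among feasible candidates
# keep the one with the smallest residual sum of squares.
nnls_enum_oracle <- function(y, X) {
  p <- ncol(X)
  best <- rep(0, p)
  best_rss <- sum(y^2)                  # the all-zero candidate
  for (size in seq_len(p)) {
    for (free in combn(p, size, simplify = FALSE)) {
      b <- tryCatch(ols_oracle(y, X[, free, drop = FALSE]),
                    error = function(e) NULL)
      if (is.null(b) || any(b < 0)) next
      cand <- rep(0, p)
      cand[free] <- b
      rss <- sum((y - X %*% cand)^2)
      if (rss < best_rss - 1e-12 ||
          (abs(rss - best_rss) <= 1e-12 && sum(cand^2) < sum(best^2))) {
        best <- cand
        best_rss <- rss
      }
    }
  }
  best
}

pearson_oracle <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}
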