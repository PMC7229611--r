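# Independent oracles used by both the unit and the acceptance suites.

# Egger: solve the ordinary-least-squares normal equations directly.
egger_oracle <- function(log_or, se) {
  y <- log_or / se
  x <- 1 / se
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  s2 <- sum(resid^2) / (length(y) - 2)
  se_b <- sqrt(diag(s2 * solve(t(X) %*% X)))
  list(intercept = unname(beta[1]), se_intercept = unname(se_b[1]))
}

# Kendall score by brute force over all pairs.
kendall_oracle <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) for (j in seq_along(x)) {
    if (i < j) s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
  }
  s
}

# Begg's standardized deviates, written out from the definition.
begg_u <- function(log_or, se) {
  w <- 1 / se^2
  (log_or - sum(w * log_or) / sum(w)) / sqrt(se^2 - 1 / sum(w))
}
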