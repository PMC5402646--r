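# Independent brute-force oracles used across the suite. These never call
# into the package paths they check.

# OLS by explicit normal equations
ols_normal_equations <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  yhat <- X %*% beta
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  n <- length(y)
  sigma2 <- ss_res / (n - 2)
  cov_beta <- sigma2 * solve(t(X) %*% X)
  se <- sqrt(diag(cov_beta))
  t_slope <- beta[2] / se[2]
  list(intercept = beta[1], slope = beta[2], r2 = 1 - ss_res / ss_tot,
       se_intercept = se[1], se_slope = se[2],
       p_slope = 2 * stats::pt(-abs(t_slope), df = n - 2),
       ci_slope = beta[2] + c(-1, 1) * stats::qt(0.975, n - 2) * se[2],
       ci_intercept = beta[1] + c(-1, 1) * stats::qt(0.975, n - 2) * se[1])
}

# Exhaustive two-sided Mann-Whitney: enumerate every assignment of the
# pooled values to sample 1, build the exact U distribution, apply the
# conventional two-sided rule.
mw_exact_enumeration <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  u_obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  r_all <- rank(pooled)
  u_dist <- apply(combos, 2, function(idx) sum(r_all[idx]) - n1 * (n1 + 1) / 2)
  centre <- n1 * n2 / 2
  p <- if (u_obs > centre) 2 * mean(u_dist >= u_obs) else 2 * mean(u_dist <= u_obs)
  list(U = u_obs, p = min(1, p))
}

# Spearman rho by direct average-rank computation (Pearson on mid-ranks)
spearman_brute <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# adjusted Fisher-Pearson skewness straight from its definition
skewness_oracle <- function(x) {
  n <- length(x)
  m2 <- sum((x - mean(x))^2) / n
  m3 <- sum((x - mean(x))^3) / n
  (m3 / m2^1.5) * sqrt(n * (n - 1)) / (n - 2)
}
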