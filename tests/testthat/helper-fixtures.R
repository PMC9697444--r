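# Shared fixtures built in code.

# Random vOCG component sets whose forward Young-Dupre angles are
# physical for all three default liquids (both acid-base roots >= 0 by
# construction).
random_components <- function(n, seed = 42) {
  set.seed(seed)
  out <- data.frame(gamma_lw = numeric(0), gamma_plus = numeric(0),
                    gamma_minus = numeric(0))
  liq <- default_liquids()
  while (nrow(out) < n) {
    cand <- data.frame(gamma_lw = runif(2 * n, 5, 50),
                       gamma_plus = runif(2 * n, 0, 4)^2,
                       gamma_minus = runif(2 * n, 0, 7)^2)
    ok <- stats::complete.cases(
      pbrsurf:::forward_cos(cand$gamma_lw, cand$gamma_plus,
                            cand$gamma_minus, liq))
    out <- rbind(out, cand[ok, ])
  }
  out[seq_len(n), ]
}

# Direct textbook one-way ANOVA (sums of squares computed explicitly),
# independent of stats::aov.
anova_oracle <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  k <- length(groups)
  n_i <- lengths(groups)
  grand <- mean(values)
  ss_between <- sum(n_i * (vapply(groups, mean, numeric(1)) - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_b <- k - 1
  df_w <- sum(n_i) - k
  f <- (ss_between / df_b) / (ss_within / df_w)
  list(f = f, p = stats::pf(f, df_b, df_w, lower.tail = FALSE),
       mse = ss_within / df_w, df_error = df_w)
}

# Ordinary least squares by explicit normal equations.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}
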