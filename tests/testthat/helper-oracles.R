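# Independent oracles used to cross-check the package's computations.

# OLS by explicit normal equations with t-distribution p-values; written
# independently of fit_linear_model() so the two routes can disagree.
ols_oracle <- function(y, X) {
  Xi <- cbind(`(Intercept)` = 1, X)
  XtX <- crossprod(Xi)
  beta <- solve(XtX, crossprod(Xi, y))
  resid <- y - Xi %*% beta
  df <- length(y) - ncol(Xi)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tstat <- drop(beta) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(beta = drop(beta), se = se, p = p, r2 = r2)
}

# Second-order delta-method approximation of E[effort / (reward * 6/11)]
# for independent effort and reward scores with the given moments.
ratio_delta_oracle <- function(effort_mean = 12.5, effort_sd = 1.9,
                               reward_mean = 48.1, reward_sd = 3.2) {
  (11 / 6) * (effort_mean / reward_mean) *
    (1 + reward_sd^2 / reward_mean^2)
}

# Moments of a categorical distribution given as a named probability vector
# (names are the levels), by direct summation.
marginal_moments <- function(p) {
  lev <- as.numeric(names(p))
  m <- sum(p * lev)
  c(mean = m, sd = sqrt(sum(p * lev^2) - m^2))
}

# Draw a valid random response matrix for property tests.
random_population <- function(n, item_specs = default_item_specs()) {
  cols <- lapply(seq_len(nrow(item_specs)), function(i) {
    sample(item_specs$min_level[i]:item_specs$max_level[i], n, replace = TRUE)
  })
  out <- do.call(cbind, cols)
  colnames(out) <- item_specs$item_id
  out
}
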