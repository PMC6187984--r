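# Independent oracles used by the unit tests.  They deliberately avoid the
# package's own linear-algebra paths: fits go through stats::lm on an
# explicitly constructed data frame.

# truncated-power design for a knot set, as a data frame for lm()
oracle_design_df <- function(T_len, knots) {
  df <- data.frame(t = seq_len(T_len))
  for (c in knots) df[[paste0("b", c)]] <- pmax(seq_len(T_len) - c, 0)
  df
}

# least-squares fit of a univariate CUSUM curve on a knot set via lm();
# returns fitted values and mse (residual sum of squares / T)
oracle_ols <- function(y, knots) {
  df <- oracle_design_df(length(y), knots)
  df$y <- y
  fml <- if (length(knots))
    stats::as.formula(paste("y ~ t +", paste(paste0("b", knots), collapse = " + ")))
  else stats::as.formula("y ~ 1")
  fit <- stats::lm(fml, data = df)
  list(fitted = unname(stats::fitted(fit)),
       mse = mean(stats::residuals(fit)^2),
       coef = stats::coef(fit))
}

# exhaustive single-knot search: the knot in 2:(T-1) minimizing the lm mse
oracle_best_knot <- function(y) {
  T_len <- length(y)
  cand <- 2:(T_len - 1)
  mses <- vapply(cand, function(c) oracle_ols(y, c)$mse, 0)
  cand[which.min(mses)]
}

# exhaustive two-knot search over all pairs (small T only)
oracle_best_pair <- function(y) {
  T_len <- length(y)
  cand <- 2:(T_len - 1)
  best <- c(NA, NA); best_mse <- Inf
  for (i in seq_along(cand)) for (j in seq_along(cand)) {
    if (j <= i) next
    m <- oracle_ols(y, c(cand[i], cand[j]))$mse
    if (m < best_mse) { best_mse <- m; best <- c(cand[i], cand[j]) }
  }
  sort(best)
}

# noiseless multivariate step series for exact-recovery checks
noiseless_series <- function(T_len, cps, weights, baseline = 0, N = 1) {
  spec <- step_model_spec(T_len, N = N, baseline = baseline, cps = cps,
                          weights = weights, sigma = 0)
  simulate_step_series(spec)
}
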