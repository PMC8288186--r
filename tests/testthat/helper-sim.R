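# small builders shared across tests

tiny_panel <- function(n = 5, freq = seq(0.2, 0.6, length.out = n), ...) {
  snp_panel(id = sprintf("snp%02d", seq_len(n)), baseline_freq = freq, ...)
}

tiny_config <- function(n_per_cohort = 300, seed = 1, ...) {
  sim_config(n_per_cohort = n_per_cohort, seed = seed, ...)
}

# flat aging schedule: +delta D per 5 years across 40-70
flat_schedule <- function(delta = 0.10) {
  data.frame(age_start = seq(40, 65, 5), age_end = seq(45, 70, 5),
             delta_spe_per_5y = delta)
}

# closed-form OLS oracle: coefficients and dosage-coefficient SE/p from
# the normal equations, independent of the package's fitting path
ols_oracle <- function(y, X) {
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(s2 * solve(XtX)))
  t <- b / se
  list(beta = drop(b), se = se, p = 2 * pt(-abs(drop(t)), df))
}
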