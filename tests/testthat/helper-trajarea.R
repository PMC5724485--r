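# Lean one-series world (identity instrument family) used for estimator
# property simulations: the monotone map is linear there, so the configured
# latent effects ARE the standardised effects on the analysed scale.
recovery_config <- function(effects = c(0, -0.3, -0.5, -0.3),
                            n_per_arm = c(intervention = 28L, control = 26L),
                            missingness = NULL, seed = 1L) {
  series <- list(score = trial_series(
    c("score_9", "score_15", "score_27", "score_39"), c(9, 15, 27, 39),
    "normal", mean = c(50, 48, 47, 46), sd = c(9, 10, 11, 12),
    effect = effects))
  if (is.null(missingness)) {
    missingness <- rbind(intervention = c(0, 0.04, 0.1, 0.04),
                         control = c(0, 0, 0.05, 0.08))
  }
  trial_config(n_per_arm = n_per_arm, series = series,
               missingness = missingness, seed = seed)
}

score_specs <- function(covariates = TRUE) {
  covs <- function(t) {
    if (covariates) c("centre", paste0("age_", t), "ethnicity",
                      "maternal_education")
    else character()
  }
  lapply(c(15, 27, 39), function(t) {
    occasion_spec(paste0(t, "m"), t, paste0("score_", t),
                  baseline_column = "score_9", baseline_time = 9,
                  covariate_columns = covs(t))
  })
}

# Direct-summation observed-data log-likelihood: each participant contributes
# the marginal normal density of their observed outcome components. Oracle
# for the compiled likelihood, independent of the EM path.
sur_loglik_R <- function(beta_list, Sigma, X, Y) {
  n <- nrow(Y)
  ll <- 0
  for (i in seq_len(n)) {
    obs <- which(!is.na(Y[i, ]))
    if (!length(obs)) next
    mu <- vapply(obs, function(k) sum(X[[k]][i, ] * beta_list[[k]]), 0)
    S <- Sigma[obs, obs, drop = FALSE]
    r <- Y[i, obs] - mu
    ll <- ll - 0.5 * (length(obs) * log(2 * pi) +
                      as.numeric(determinant(S)$modulus) +
                      drop(t(r) %*% solve(S, r)))
  }
  ll
}

# sample of size n with mean and sd matched exactly
scaled_sample <- function(n, mean, sd) {
  v <- rnorm(n)
  (v - base::mean(v)) / stats::sd(v) * sd + mean
}

# hand-built effect_trajectory for direct area tests
manual_trajectory <- function(times, d, cov_d) {
  K <- length(times)
  traj <- data.frame(label = paste0("t", seq_len(K)), time = times, d = d,
                     se = sqrt(pmax(diag(cov_d), 0)),
                     sd_within = NA_real_, beta = d)
  attr(traj, "cov") <- cov_d
  class(traj) <- c("effect_trajectory", "data.frame")
  traj
}
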