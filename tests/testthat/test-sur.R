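complete_score_data <- function(n_per_arm = c(intervention = 40L,
                                              control = 40L), seed = 13) {
  miss <- rbind(intervention = rep(0, 4), control = rep(0, 4))
  generate_trial(recovery_config(missingness = miss,
                                 n_per_arm = n_per_arm, seed = seed))
}

test_that("apply_transform follows its contract", {
  expect_identical(apply_transform(0, "log1p"), 0)
  expect_equal(apply_transform(6.32, "log1p"), log(7.32), tolerance = 1e-12)
  v <- c(3.2, NA, 0.5)
  expect_identical(apply_transform(v, "identity"), v)
  expect_identical(is.na(apply_transform(v, "log1p")), is.na(v))
  expect_error(apply_transform(c(1, -2, 3), "log1p"), "rows: 2")
})

test_that("complete data with identical regressors reduces to equation-wise OLS", {
  d <- complete_score_data()
  specs <- score_specs()
  # identical regressor sets: same covariates in every equation
  for (k in seq_along(specs)) {
    specs[[k]]$covariate_columns <- c("centre", "age_15", "ethnicity",
                                      "maternal_education")
  }
  fit <- fit_sur(d, specs)
  expect_true(fit$converged)
  for (k in seq_along(specs)) {
    s <- specs[[k]]
    df <- data.frame(y = d[[s$outcome_column]],
                     treat = as.numeric(d$arm == "intervention"),
                     baseline = d$score_9, centre = factor(d$centre),
                     age = d$age_15, eth = factor(d$ethnicity),
                     edu = d$maternal_education)
    ols <- stats::lm(y ~ treat + baseline + centre + age + eth + edu,
                     data = df)
    expect_equal(unname(fit$coefficients[[k]]),
                 unname(stats::coef(ols)), tolerance = 1e-8)
  }
})

test_that("a single-equation fit matches the closed-form normal equations", {
  d <- complete_score_data(seed = 31)
  spec <- score_specs()[2]
  fit <- fit_sur(d, spec)
  X <- cbind(1, as.numeric(d$arm == "intervention"), d$score_9,
             as.numeric(factor(d$centre)) - 1, d$age_27,
             as.numeric(factor(d$ethnicity)) - 1, d$maternal_education)
  beta_hat <- solve(crossprod(X), crossprod(X, d$score_27))
  expect_equal(unname(fit$coefficients[[1]]), drop(beta_hat),
               tolerance = 1e-10)
})

test_that("adding a constant to one outcome shifts only that intercept", {
  d <- complete_score_data(seed = 7)
  specs <- score_specs()
  f1 <- fit_sur(d, specs)
  d2 <- d
  d2$score_27 <- d2$score_27 + 100
  f2 <- fit_sur(d2, specs)
  c1 <- f1$coefficients; c2 <- f2$coefficients
  expect_equal(c2[["27m"]]["(Intercept)"] - c1[["27m"]]["(Intercept)"],
               c(`(Intercept)` = 100), tolerance = 1e-8)
  c2[["27m"]]["(Intercept)"] <- c1[["27m"]]["(Intercept)"]
  expect_equal(unlist(c2), unlist(c1), tolerance = 1e-8)
})

test_that("FIML solution maximises the brute-force observed-data likelihood", {
  set.seed(42)
  n <- 18
  X1 <- cbind(1, rbinom(n, 1, 0.5), rnorm(n))
  X2 <- cbind(1, X1[, 2], rnorm(n))
  S_true <- matrix(c(1, 0.6, 0.6, 1.4), 2)
  E <- matrix(rnorm(2 * n), n, 2) %*% chol(S_true)
  Y <- cbind(X1 %*% c(1, -0.5, 0.3), X2 %*% c(2, -0.2, 0.1)) + E
  Y[sample(n, 4), 2] <- NA
  Y[sample(n, 2), 1] <- NA

  X <- list(X1, X2)
  st <- list(beta0 = list(c(0, 0, 0), c(0, 0, 0)), Sigma0 = diag(2))
  res <- trajarea:::fiml_em_cpp(X, Y, st$beta0, st$Sigma0, 2000L, 1e-12)
  expect_true(res$converged)
  beta_hat <- lapply(res$beta, as.numeric)

  # compiled likelihood agrees with direct summation at the optimum
  ll_R <- sur_loglik_R(beta_hat, res$Sigma, X, Y)
  expect_equal(res$loglik, ll_R, tolerance = 1e-8)

  # monotone ascent: optimum beats the starting value
  expect_gt(res$loglik, sur_loglik_R(st$beta0, st$Sigma0, X, Y))

  # a general-purpose optimiser started elsewhere finds no better value
  unpack <- function(p) {
    b <- list(p[1:3], p[4:6])
    L <- matrix(0, 2, 2)
    L[1, 1] <- exp(p[7]); L[2, 1] <- p[8]; L[2, 2] <- exp(p[9])
    list(beta = b, Sigma = L %*% t(L))
  }
  nll <- function(p) {
    pr <- unpack(p)
    -sur_loglik_R(pr$beta, pr$Sigma, X, Y)
  }
  opt <- optim(c(0.5, 0, 0, 1.5, 0, 0, 0, 0.2, 0), nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_lt(-opt$value, res$loglik + 1e-6)
  pr <- unpack(opt$par)
  expect_equal(unlist(pr$beta), unlist(beta_hat), tolerance = 1e-3)
})

test_that("likelihood is monotone along the EM path on trial-scale data", {
  d <- generate_trial(recovery_config(seed = 77))
  specs <- score_specs()
  design <- trajarea:::build_sur_design(d, specs)
  st <- trajarea:::sur_start(design)
  fit <- fit_sur(d, specs)
  ll0 <- sur_loglik_R(st$beta0, st$Sigma0, design$X,
                      design$Y)
  expect_true(fit$converged)
  expect_gte(fit$loglik, ll0)
  # ... and the reported likelihood is the observed-data likelihood
  expect_equal(fit$loglik,
               sur_loglik_R(lapply(fit$coefficients, unname), fit$Sigma,
                            design$X, design$Y),
               tolerance = 1e-8)
})

test_that("degenerate designs are rejected with diagnostics", {
  d <- complete_score_data(seed = 3)
  specs <- score_specs()
  d2 <- d
  d2$score_27 <- NA_real_
  expect_error(fit_sur(d2, specs), "all outcomes missing")
  d3 <- d
  d3$dup <- d3$score_9  # duplicate of the baseline covariate
  specs3 <- specs
  specs3[[1]]$covariate_columns <- c(specs3[[1]]$covariate_columns, "dup")
  expect_error(fit_sur(d3, specs3), "collinear.*dup")
  specs4 <- score_specs()
  expect_error(occasion_spec("bad", 15, "score_15",
                             baseline_column = "score_39",
                             baseline_time = 39,
                             covariate_columns = character()),
               "must precede")
})

test_that("covariate-incomplete participants are dropped with a warning", {
  d <- complete_score_data(seed = 19)
  d$maternal_education[3] <- NA
  expect_warning(fit <- fit_sur(d, score_specs()), "dropped")
  expect_equal(fit$n_used, nrow(d) - 1)
  expect_equal(fit$n_dropped, 1L)
})
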