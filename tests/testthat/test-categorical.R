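trial_diag_table <- rbind(intervention = c(16, 7, 4),
                          control = c(16, 8, 2))

test_that("exact 2xK test reproduces the trial's diagnostic-outcome p", {
  p <- fisher_freeman_halton(trial_diag_table)
  expect_equal(round(p, 3), 0.846)
})

test_that("exact test degenerate and 2x2 cases match enumeration oracles", {
  expect_equal(fisher_freeman_halton(rbind(c(5, 3, 2), c(5, 3, 2))), 1.0,
               tolerance = 1e-12)

  # independent 2x2 oracle: direct hypergeometric sum over the support
  tab <- rbind(c(3, 7), c(8, 2))
  r1 <- 10; c1 <- 11; N <- 20
  support <- max(0, c1 - (N - r1)):min(r1, c1)
  probs <- dhyper(support, c1, N - c1, r1)
  p_obs <- dhyper(3, c1, N - c1, r1)
  oracle <- sum(probs[probs <= p_obs + 1e-12])
  expect_equal(fisher_freeman_halton(tab), oracle, tolerance = 1e-12)

  # and the stats::fisher.test reference on the 2x3 table
  expect_equal(fisher_freeman_halton(trial_diag_table),
               fisher.test(trial_diag_table)$p.value, tolerance = 1e-9)
})

test_that("exact test is invariant to row swap and column permutation", {
  perms <- list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1), c(3, 2, 1))
  p0 <- fisher_freeman_halton(trial_diag_table)
  for (pm in perms) {
    expect_equal(fisher_freeman_halton(trial_diag_table[, pm]), p0,
                 tolerance = 1e-12)
    expect_equal(fisher_freeman_halton(trial_diag_table[2:1, pm]), p0,
                 tolerance = 1e-12)
  }
  expect_error(fisher_freeman_halton(rbind(c(300, 300), c(200, 250))),
               "guard")
})

test_that("proportional-odds OR reproduces the trial's ordinal result", {
  res <- diagnostic_outcome_tests(trial_diag_table,
                                  indicator_arm = "control")
  expect_equal(round(res$proportional_odds$or, 2), 0.83)
  expect_equal(round(res$proportional_odds$p, 3), 0.726, tolerance = 0.002)
  expect_equal(round(res$fisher_p, 3), 0.846)
})

test_that("proportional-odds model satisfies its closed-form and symmetry contracts", {
  # identical distributions in both arms -> OR = 1
  y <- rep(rep(1:3, c(10, 6, 4)), 2)
  x <- rep(c(0, 1), each = 20)
  expect_equal(proportional_odds(y, x)$or, 1, tolerance = 1e-6)

  # two-level outcome: OR of the higher category equals the 2x2 odds ratio
  tab22 <- rbind(c(12, 8), c(6, 14))
  y2 <- rep(rep(1:2, 2), as.vector(t(tab22)))
  x2 <- rep(c(0, 1), rowSums(tab22))
  fit2 <- proportional_odds(y2, x2)
  expect_equal(fit2$or, (14 / 6) / (8 / 12), tolerance = 1e-6)

  # flipping the indicator inverts the odds ratio
  yo <- rep(rep(1:3, 2), as.vector(t(trial_diag_table)))
  xo <- rep(c(1, 0), rowSums(trial_diag_table))
  f1 <- proportional_odds(yo, xo)
  f2 <- proportional_odds(yo, 1 - xo)
  expect_equal(f1$or, 1 / f2$or, tolerance = 1e-8)

  # complete separation is reported, not silently returned
  ys <- rep(c(1, 3), each = 10)
  xs <- rep(c(0, 1), each = 10)
  expect_error(proportional_odds(ys, xs), "separation|converge")
})

test_that("proportional-odds matches an established implementation", {
  skip_if_not_installed("MASS")
  y <- factor(rep(rep(c("a", "b", "c"), 2), as.vector(t(trial_diag_table))),
              levels = c("a", "b", "c"), ordered = TRUE)
  x <- rep(c(0, 1), rowSums(trial_diag_table))
  ours <- proportional_odds(y, x)
  ref <- MASS::polr(y ~ x, Hess = TRUE)
  expect_equal(ours$beta, unname(coef(ref)), tolerance = 1e-5)
  expect_equal(ours$se, sqrt(vcov(ref)["x", "x"]), tolerance = 1e-4)
})

test_that("intraclass correlations match hand ANOVA computations", {
  # identical coders -> both coefficients are exactly 1
  r <- cbind(c(3, 5, 2, 6, 4, 1), c(3, 5, 2, 6, 4, 1))
  expect_equal(icc_oneway(r), 1, tolerance = 1e-12)
  expect_equal(icc_agreement(r), 1, tolerance = 1e-12)

  # 6-subject toy table against a from-scratch ANOVA decomposition
  m <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
  n <- 6; k <- 2
  grand <- mean(m)
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  mse <- (sum((m - grand)^2) - (n - 1) * msr - (k - 1) * msc) /
         ((n - 1) * (k - 1))
  msw <- sum((m - rowMeans(m))^2) / (n * (k - 1))
  expect_equal(icc_oneway(m), (msr - msw) / (msr + msw), tolerance = 1e-10)
  expect_equal(icc_agreement(m),
               (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
               tolerance = 1e-10)

  # independent coders -> both near zero at large n
  set.seed(10)
  big <- cbind(rnorm(10000), rnorm(10000))
  expect_lt(abs(icc_oneway(big)), 0.03)
  expect_lt(abs(icc_agreement(big)), 0.03)
})

test_that("absolute agreement penalises a systematic coder offset", {
  set.seed(3)
  subj <- rnorm(30, sd = 2)
  r <- cbind(subj + rnorm(30, sd = 0.3), subj + 1.5 + rnorm(30, sd = 0.3))
  a <- rating_consistency_oracle <- local({
    aov <- trajarea:::rating_anova(r)
    (aov$msr - aov$mse) / (aov$msr + aov$mse)
  })
  expect_lt(icc_agreement(r), rating_consistency_oracle)
  expect_error(icc_oneway(cbind(rep(2, 5), rep(2, 5))), "undefined")
  expect_error(icc_oneway(cbind(c(1, 2), c(1, 2))), "at least 3")
  expect_error(icc_agreement(cbind(c(1, NA, 2), c(1, 2, 3))), "complete")
})
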