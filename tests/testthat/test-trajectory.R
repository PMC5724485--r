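test_that("pooled within-group SD and raw d match the two-cell hand formula", {
  # cells mirroring a published follow-up contrast: 25 vs 23 children with
  # means 6.32 / 4.13 and SDs 6.79 / 3.61 on the same instrument
  set.seed(1)
  y <- c(scaled_sample(25, 6.32, 6.79), scaled_sample(23, 4.13, 3.61))
  arm <- rep(c("control", "intervention"), c(25, 23))
  s_w <- trajarea:::pooled_within_sd(y, arm)
  expect_equal(s_w, sqrt((24 * 6.79^2 + 22 * 3.61^2) / 46), tolerance = 1e-10)
  expect_equal(round(s_w, 3), 5.503)
  d_raw <- (4.13 - 6.32) / s_w
  expect_equal(round(d_raw, 3), -0.398)
})

test_that("standardisation contract: zero beta, scale invariance, stratified SD", {
  # zero coefficient -> zero d regardless of the SD used
  set.seed(2)
  Y <- matrix(rnorm(80, sd = 5), 40, 2)
  arm <- rep(c("intervention", "control"), 20)
  tr <- trajarea:::standardize_core(c(0, 1.2), diag(c(0.5, 0.5)),
                                    c(15, 27), c("15m", "27m"), Y, arm,
                                    NULL, baseline_time = 9)
  expect_identical(tr$d[tr$label == "15m"], 0)
  expect_identical(tr$d[tr$label == "baseline"], 0)
  expect_true(!is.unsorted(tr$time, strictly = TRUE))

  # multiplying an outcome and its baseline covariate by 10 leaves d alone
  d <- generate_trial(recovery_config(seed = 15))
  specs <- score_specs()
  t1 <- standardize(fit_sur(d, specs))
  d2 <- d
  for (cc in paste0("score_", c(9, 15, 27, 39))) d2[[cc]] <- 10 * d2[[cc]]
  t2 <- standardize(fit_sur(d2, specs))
  expect_equal(t2$d, t1$d, tolerance = 1e-10)
  expect_equal(t2$se, t1$se, tolerance = 1e-10)

  # stratified SD pools cells by degrees of freedom
  y <- c(scaled_sample(10, 0, 2), scaled_sample(12, 5, 3))
  strat <- rep(c("m1", "m2"), c(10, 12))
  s <- trajarea:::pooled_within_sd(y, rep("control", 22), strat)
  expect_equal(s, sqrt((9 * 4 + 11 * 9) / 20), tolerance = 1e-10)
})

test_that("degenerate within-group SD is an error naming the occasion", {
  Y <- cbind(rep(1, 20), rnorm(20))
  arm <- rep(c("intervention", "control"), 10)
  expect_error(
    trajarea:::standardize_core(c(0.5, 0.5), diag(2), c(15, 27),
                                c("15m", "27m"), Y, arm, NULL, 9),
    "'15m'.*SD")
})

test_that("trapezium area matches hand computation and numeric integration", {
  times <- c(9, 15, 27, 39)
  d <- c(0, -0.2, -0.5, -0.3)
  C <- diag(c(0, 1, 1, 1)) * 0.04
  a <- area_between_curves(manual_trajectory(times, d, C))
  expect_equal(a$area, -9.6, tolerance = 1e-12)
  expect_equal(a$averaged_es, -0.32, tolerance = 1e-12)
  expect_equal(unname(a$weights), c(3, 9, 12, 6))
  expect_equal(sum(a$weights), a$span)

  # oracle: numeric integration of the piecewise-linear interpolant
  f <- approxfun(times, d)
  oracle <- integrate(f, 9, 39, subdivisions = 1000, rel.tol = 1e-13)$value
  expect_equal(a$area, oracle, tolerance = 1e-10)

  # constant trajectory: averaged ES is exactly that constant
  for (const in c(-0.4, 0.7)) {
    ac <- area_between_curves(manual_trajectory(c(9, 15, 27, 39),
                                                rep(const, 4), diag(4)))
    expect_equal(ac$averaged_es, const, tolerance = 1e-14)
  }
})

test_that("area variance expands w' Cov w; anchored baseline drops out", {
  v <- 0.07
  C <- diag(c(0, v, v, v))
  a <- area_between_curves(manual_trajectory(c(9, 15, 27, 39),
                                             c(0, -0.2, -0.5, -0.3), C))
  expect_equal(a$se_area^2, 261 * v, tolerance = 1e-12)
})

test_that("area is linear in d: doubling d doubles area and z", {
  C <- diag(c(0, 0.05, 0.06, 0.04))
  t1 <- manual_trajectory(c(9, 15, 27, 39), c(0, -0.2, -0.5, -0.3), C)
  t2 <- manual_trajectory(c(9, 15, 27, 39), 2 * c(0, -0.2, -0.5, -0.3), C)
  a1 <- area_between_curves(t1)
  a2 <- area_between_curves(t2)
  expect_equal(a2$area, 2 * a1$area, tolerance = 1e-12)
  expect_equal(a2$z, 2 * a1$z, tolerance = 1e-12)
})

test_that("unordered times and degenerate covariance are rejected", {
  expect_error(area_between_curves(
    manual_trajectory(c(15, 9, 27), c(0, 1, 2), diag(3))),
    "strictly increasing")
  expect_error(area_between_curves(
    manual_trajectory(c(9, 15, 27), c(0, 1, 2), matrix(0, 3, 3))),
    "zero variance|degenerate")
})

test_that("leave-one-out areas behave under exchangeability and outliers", {
  d <- generate_trial(recovery_config(
    effects = rep(0, 4),
    n_per_arm = c(intervention = 14L, control = 12L),
    missingness = rbind(intervention = rep(0, 4), control = rep(0, 4)),
    seed = 4))
  specs <- score_specs(covariates = FALSE)

  # duplicated participant: omitting either copy gives the same area
  d_dup <- rbind(d, d[7, ])
  d_dup$participant_id[nrow(d_dup)] <- "P_copy"
  i1 <- 7; i2 <- nrow(d_dup)
  loo <- leave_one_out_areas(d_dup, specs)
  expect_equal(loo$area[i1], loo$area[i2], tolerance = 1e-6)

  # a planted extreme outlier dominates the case-wise deviations
  d_out <- d
  d_out[2, paste0("score_", c(15, 27, 39))] <- c(200, 500, 600)
  loo2 <- leave_one_out_areas(d_out, specs)
  expect_true(all(loo2$converged))
  expect_true(all(is.finite(loo2$area)))
  dev <- abs(loo2$area - attr(loo2, "full_area"))
  expect_equal(which.max(dev), 2L)
})
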