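#' Bootstrap confidence interval for the area effect size
#'
#' Resamples participants with replacement — stratified by arm, preserving
#' the allocation — and reruns the full pipeline (joint ML fit,
#' standardisation, trapezium area) on each replicate. Percentile intervals
#' are formed from the converged replicates; their endpoints are order
#' statistics of the replicate values. Replicates whose fit fails to
#' converge are dropped and counted.
#'
#' @param dataset wide trial table.
#' @param specs list of [occasion_spec()]s.
#' @param B number of replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed; fixed seed gives identical intervals.
#' @param force proceed even if more than 20\% of replicates fail.
#' @param max_iter,tol passed to the joint fit.
#' @return object of class `bootstrap_result`: point estimates, replicate
#'   `areas` and `averaged_es` values, percentile `ci_area` / `ci_averaged`,
#'   `n_requested`, `n_converged`, `seed`.
#' @export
bootstrap_area <- function(dataset, specs, B = 1000, level = 0.95,
                           seed = 1L, force = FALSE,
                           max_iter = 500, tol = 1e-8) {
  stopifnot(B >= 1, level > 0, level < 1)
  design <- build_sur_design(dataset, specs)
  full <- fit_sur_core(design, specs, max_iter = max_iter, tol = tol)
  if (!full$converged) stop("full-data fit did not converge")
  point <- area_between_curves(standardize(full))
  warm <- list(beta0 = lapply(full$coefficients, unname),
               Sigma0 = full$Sigma)
  arm <- design$arm
  idx_by_arm <- split(seq_along(arm), arm)
  baseline_time <- min(vapply(specs, `[[`, 0, "baseline_time"))
  times <- vapply(specs, `[[`, 0, "time")
  labels <- vapply(specs, `[[`, "", "label")
  has_strata <- any(!vapply(specs, function(s)
    is.null(s$sd_stratum_column), TRUE))

  areas <- rep(NA_real_, B)
  avgs <- rep(NA_real_, B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- unlist(lapply(idx_by_arm, function(ii)
        ii[sample.int(length(ii), length(ii), replace = TRUE)]),
        use.names = FALSE)
      des_b <- list(
        Y = design$Y[idx, , drop = FALSE],
        X = lapply(design$X, function(x) x[idx, , drop = FALSE]),
        arm = arm[idx],
        treat_pos = design$treat_pos,
        coef_names = design$coef_names,
        strata = if (has_strata) lapply(design$strata, function(s) s[idx])
                 else NULL,
        n_dropped = 0L)
      # replicates that resample themselves into a degenerate design
      # (collinear covariates, singular information) count as failures
      res <- tryCatch(suppressWarnings({
        f <- fit_sur_core(des_b, specs, max_iter = max_iter, tol = tol,
                          start = warm)
        if (!f$converged || anyNA(f$vcov)) NULL else {
          tr <- treatment_effects(f)
          traj <- standardize_core(tr$beta, attr(tr, "cov"), times, labels,
                                   des_b$Y, des_b$arm, des_b$strata,
                                   baseline_time)
          area_between_curves(traj)
        }
      }), error = function(e) NULL)
      if (!is.null(res)) {
        areas[b] <- res$area
        avgs[b] <- res$averaged_es
      }
    }
  })
  ok <- is.finite(areas)
  n_conv <- sum(ok)
  if (n_conv < 0.8 * B && !force) {
    stop(sprintf("%d of %d bootstrap replicates failed; rerun with force = TRUE to accept",
                 B - n_conv, B))
  }
  alpha <- (1 - level) / 2
  ci <- function(v) unname(quantile(v[ok], c(alpha, 1 - alpha), type = 1))
  structure(list(area = point$area, averaged_es = point$averaged_es,
                 areas = areas, averaged = avgs,
                 ci_area = ci(areas), ci_averaged = ci(avgs),
                 level = level, n_requested = B, n_converged = n_conv,
                 seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Participant bootstrap (%d/%d replicates converged)\n",
              x$n_converged, x$n_requested))
  cat(sprintf("  averaged ES = %.3f, %d%% percentile CI [%.3f, %.3f]\n",
              x$averaged_es, round(100 * x$level),
              x$ci_averaged[1], x$ci_averaged[2]))
  invisible(x)
}
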