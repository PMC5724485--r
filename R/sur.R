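#' Specify one assessment occasion for the joint regressions
#'
#' Each post-baseline occasion contributes one regression equation: the
#' (possibly transformed) outcome at that occasion on treatment arm, the
#' relevant baseline measure value, and the prespecified covariates. The
#' baseline occasion itself is not an equation; it anchors the standardised
#' trajectory at zero and supplies the baseline covariate.
#'
#' @param label short name for the occasion (e.g. `"15m"`).
#' @param time assessment age in months.
#' @param outcome_column outcome column at this occasion.
#' @param transform `"identity"` or `"log1p"` (right-skewed symptom totals).
#' @param baseline_column baseline measure column used as covariate.
#' @param baseline_time age of the baseline occasion; must precede `time`.
#' @param covariate_columns additional adjustment columns. Character columns
#'   enter as factor indicators, numeric columns (including ordinal
#'   qualification bands) as given. The per-occasion age column is usually
#'   among them.
#' @param treatment_column arm column; coded 1 = intervention internally.
#' @param sd_stratum_column optional column defining extra strata for the
#'   within-group SD used in standardisation (e.g. assessment module at the
#'   last occasion).
#' @return an object of class `occasion_spec`.
#' @export
occasion_spec <- function(label, time, outcome_column,
                          transform = c("identity", "log1p"),
                          baseline_column, baseline_time,
                          covariate_columns = character(),
                          treatment_column = "arm",
                          sd_stratum_column = NULL) {
  transform <- match.arg(transform)
  stopifnot(is.numeric(time), length(time) == 1,
            is.numeric(baseline_time), length(baseline_time) == 1)
  if (baseline_time >= time) {
    stop("occasion '", label, "': baseline occasion (", baseline_time,
         ") must precede the outcome occasion (", time, ")")
  }
  if (is.null(treatment_column) || !nzchar(treatment_column)) {
    stop("occasion '", label, "': treatment_column is required")
  }
  structure(list(label = label, time = time,
                 outcome_column = outcome_column, transform = transform,
                 baseline_column = baseline_column,
                 baseline_time = baseline_time,
                 covariate_columns = covariate_columns,
                 treatment_column = treatment_column,
                 sd_stratum_column = sd_stratum_column),
            class = "occasion_spec")
}

# Build the joint design: one outcome column and one design matrix per
# occasion, restricted to covariate-complete participants. Outcomes may be
# missing (FIML handles them); covariates and baseline values may not.
build_sur_design <- function(dataset, specs) {
  stopifnot(length(specs) >= 1)
  for (s in specs) {
    need <- c(s$outcome_column, s$baseline_column, s$covariate_columns,
              s$treatment_column, s$sd_stratum_column)
    miss <- setdiff(need, names(dataset))
    if (length(miss)) {
      stop("occasion '", s$label, "': columns not in dataset: ",
           paste(miss, collapse = ", "))
    }
  }
  covar_cols <- unique(unlist(lapply(specs, function(s)
    c(s$baseline_column, s$covariate_columns, s$treatment_column))))
  keep <- complete.cases(dataset[covar_cols])
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    warning(n_dropped, " participant(s) dropped for missing covariate or ",
            "baseline values")
  }
  dat <- dataset[keep, , drop = FALSE]
  n <- nrow(dat)

  K <- length(specs)
  Y <- matrix(NA_real_, n, K)
  X <- vector("list", K)
  treat_pos <- integer(K)
  coef_names <- vector("list", K)
  for (k in seq_len(K)) {
    s <- specs[[k]]
    Y[, k] <- apply_transform(dat[[s$outcome_column]], s$transform)
    if (all(is.na(Y[, k]))) {
      stop("occasion '", s$label, "': all outcomes missing")
    }
    treat <- as.numeric(dat[[s$treatment_column]] == "intervention")
    mm_dat <- dat[, s$covariate_columns, drop = FALSE]
    for (nm in names(mm_dat)) {
      if (is.character(mm_dat[[nm]])) mm_dat[[nm]] <- factor(mm_dat[[nm]])
    }
    mm <- if (ncol(mm_dat)) {
      model.matrix(~ ., data = mm_dat)[, -1, drop = FALSE]
    } else {
      matrix(nrow = n, ncol = 0)
    }
    Xk <- cbind(`(Intercept)` = 1, treat = treat,
                baseline = as.numeric(dat[[s$baseline_column]]), mm)
    n_obs_k <- sum(!is.na(Y[, k]))
    if (n_obs_k <= ncol(Xk)) {
      stop("occasion '", s$label, "': ", n_obs_k,
           " observed outcomes for ", ncol(Xk), " predictors")
    }
    qrx <- qr(Xk)
    if (qrx$rank < ncol(Xk)) {
      drop_cols <- colnames(Xk)[qrx$pivot[(qrx$rank + 1):ncol(Xk)]]
      stop("occasion '", s$label, "': collinear design; involved columns: ",
           paste(drop_cols, collapse = ", "))
    }
    X[[k]] <- Xk
    treat_pos[k] <- 2L
    coef_names[[k]] <- colnames(Xk)
  }
  strata <- lapply(specs, function(s) {
    if (is.null(s$sd_stratum_column)) rep("all", n)
    else as.character(dat[[s$sd_stratum_column]])
  })
  list(Y = Y, X = X, arm = dat[[specs[[1]]$treatment_column]],
       treat_pos = treat_pos, coef_names = coef_names, strata = strata,
       data = dat, n_dropped = n_dropped)
}

# Equation-wise least-squares starting values and a residual-moment start
# for the cross-equation covariance.
sur_start <- function(design) {
  K <- length(design$X)
  n <- nrow(design$Y)
  beta0 <- vector("list", K)
  Res <- matrix(NA_real_, n, K)
  for (k in seq_len(K)) {
    obs <- !is.na(design$Y[, k])
    fit <- lm.fit(design$X[[k]][obs, , drop = FALSE], design$Y[obs, k])
    beta0[[k]] <- unname(fit$coefficients)
    Res[obs, k] <- fit$residuals
  }
  S <- suppressWarnings(stats::cov(Res, use = "pairwise.complete.obs"))
  dvar <- diag(S)
  dvar[!is.finite(dvar) | dvar <= 0] <- 1
  S[!is.finite(S)] <- 0
  diag(S) <- dvar
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8 * max(ev)) S <- diag(dvar, K)
  list(beta0 = beta0, Sigma0 = S)
}

#' Jointly fit occasion-specific treatment-effect regressions
#'
#' Estimates a system of seemingly unrelated regressions — one equation per
#' post-baseline occasion, each with its own predictors and error variance,
#' errors correlated across equations within participant — by maximum
#' likelihood under a joint normal model. Participants with incomplete
#' outcome records contribute the marginal likelihood of whatever they were
#' observed on (full-information ML), so no outcome-incomplete participant
#' is discarded. Estimation is by an expectation-maximisation scheme whose
#' observed-data log-likelihood is monotone; with complete data and
#' identical regressors it reproduces equation-wise least squares.
#'
#' @param dataset wide trial table (see [generate_trial()]/[read_trial()]).
#' @param specs list of [occasion_spec()]s, ordered by time.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param df_correct apply a small-sample degrees-of-freedom factor
#'   `n / (n - p̄)` (mean parameters per equation) to the coefficient
#'   covariance, compensating the ML residual-covariance bias in Wald
#'   inference at trial-scale n.
#' @return object of class `fitted_sur`: per-equation `coefficients`,
#'   joint coefficient covariance `vcov`, residual covariance `Sigma`,
#'   `loglik`, per-equation `n_obs`, `converged`, `iterations`.
#' @export
fit_sur <- function(dataset, specs, max_iter = 500, tol = 1e-8,
                    df_correct = TRUE) {
  design <- build_sur_design(dataset, specs)
  fit_sur_core(design, specs, max_iter = max_iter, tol = tol,
               df_correct = df_correct)
}

fit_sur_core <- function(design, specs, max_iter = 500, tol = 1e-8,
                         df_correct = TRUE, start = NULL) {
  if (is.null(start)) start <- sur_start(design)
  res <- fiml_em_cpp(design$X, design$Y, start$beta0, start$Sigma0,
                     as.integer(max_iter), tol)
  K <- length(design$X)
  coefs <- vector("list", K)
  for (k in seq_len(K)) {
    coefs[[k]] <- setNames(as.numeric(res$beta[[k]]), design$coef_names[[k]])
  }
  names(coefs) <- vapply(specs, `[[`, "", "label")
  pk <- vapply(design$X, ncol, 0L)
  off <- cumsum(c(0L, pk[-K]))
  treat_idx <- off + design$treat_pos
  n <- nrow(design$Y)
  cdf <- if (df_correct) n / (n - mean(pk)) else 1
  vc <- tryCatch(cdf * solve(res$info), error = function(e) {
    warning("coefficient information matrix is singular; covariance set to NA")
    matrix(NA_real_, sum(pk), sum(pk))
  })
  structure(list(coefficients = coefs, vcov = vc, Sigma = res$Sigma,
                 loglik = res$loglik, n_obs = as.integer(res$n_obs),
                 converged = isTRUE(res$converged),
                 iterations = res$iterations,
                 treat_idx = treat_idx, specs = specs,
                 n_used = n, n_dropped = design$n_dropped,
                 design = design),
            class = "fitted_sur")
}

#' @export
print.fitted_sur <- function(x, ...) {
  cat("Joint ML fit of", length(x$coefficients), "occasion regressions\n")
  cat("  participants used:", x$n_used,
      if (x$n_dropped) paste0("(", x$n_dropped, " dropped)") else "", "\n")
  cat("  log-likelihood:", format(x$loglik), " iterations:", x$iterations,
      if (!x$converged) "(NOT converged)" else "", "\n")
  tr <- treatment_effects(x)
  cat("  treatment coefficients:\n")
  print(tr)
  invisible(x)
}

#' Extract occasion-specific treatment coefficients and their covariance
#'
#' @param fit a `fitted_sur`.
#' @return data.frame with `label`, `time`, `beta`, `se`; the coefficient
#'   covariance across occasions is attached as attribute `"cov"`.
#' @export
treatment_effects <- function(fit) {
  stopifnot(inherits(fit, "fitted_sur"))
  Vt <- fit$vcov[fit$treat_idx, fit$treat_idx, drop = FALSE]
  out <- data.frame(
    label = names(fit$coefficients),
    time = vapply(fit$specs, `[[`, 0, "time"),
    beta = vapply(fit$coefficients, function(b) unname(b["treat"]), 0),
    se = sqrt(pmax(diag(Vt), 0)),
    row.names = NULL)
  attr(out, "cov") <- Vt
  out
}
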