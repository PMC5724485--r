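# Pooled within-group SD of observed (transformed) outcomes at one occasion:
# arm cells (crossed with an optional stratum, e.g. assessment module) are
# pooled by their degrees of freedom.
pooled_within_sd <- function(y, arm, stratum = NULL) {
  obs <- !is.na(y)
  g <- if (is.null(stratum)) arm[obs] else paste(arm[obs], stratum[obs])
  yv <- y[obs]
  cells <- split(yv, g)
  cells <- cells[vapply(cells, length, 0L) >= 2]
  if (!length(cells)) return(NA_real_)
  df <- vapply(cells, length, 0L) - 1L
  ss <- vapply(cells, function(v) sum((v - mean(v))^2), 0)
  sqrt(sum(ss) / sum(df))
}

# Shared core: turn treatment coefficients into an anchored standardised
# trajectory. Exposed internally so the bootstrap can reuse prebuilt pieces.
standardize_core <- function(beta, cov_beta, times, labels, Y, arm, strata,
                             baseline_time) {
  K <- length(beta)
  s_w <- numeric(K)
  for (k in seq_len(K)) {
    s_w[k] <- pooled_within_sd(Y[, k], arm, if (is.null(strata)) NULL
                               else strata[[k]])
    if (!is.finite(s_w[k]) || s_w[k] <= 0) {
      stop("occasion '", labels[k],
           "': within-group SD is zero or undefined; cannot standardise")
    }
  }
  d <- beta / s_w
  Dinv <- diag(1 / s_w, K)
  cov_d <- Dinv %*% cov_beta %*% Dinv
  # prepend the baseline anchor (randomisation implies zero expected
  # difference at baseline; it carries no sampling variance)
  traj <- data.frame(
    label = c("baseline", labels),
    time = c(baseline_time, times),
    d = c(0, d),
    se = c(0, sqrt(pmax(diag(cov_d), 0))),
    sd_within = c(NA_real_, s_w),
    beta = c(0, beta),
    row.names = NULL)
  C <- matrix(0, K + 1, K + 1)
  C[-1, -1] <- cov_d
  o <- order(traj$time)
  traj <- traj[o, , drop = FALSE]
  rownames(traj) <- NULL
  attr(traj, "cov") <- C[o, o, drop = FALSE]
  attr(traj, "sign_convention") <- "negative d = symptom reduction (benefit) for severity outcomes"
  class(traj) <- c("effect_trajectory", "data.frame")
  traj
}

#' Standardise occasion-specific treatment effects to Cohen's d
#'
#' Divides each occasion's treatment coefficient by the pooled within-group
#' standard deviation of the (transformed) outcome observed at that occasion
#' — pooling the two arm cells, and additionally the SD-stratum cells when an
#' occasion sets one (e.g. within assessment module at the last follow-up) —
#' so that effects measured on different instruments become comparable.
#' The baseline occasion is anchored at d = 0. Standard errors scale the
#' coefficient standard errors by the same constants (SDs treated as known);
#' full sampling uncertainty is delegated to the participant bootstrap.
#'
#' @param fit a [fit_sur()] result.
#' @return an `effect_trajectory`: per-occasion `time`, `d`, `se`,
#'   `sd_within`, `beta`, sorted by time, with the covariance of the d's as
#'   attribute `"cov"`.
#' @export
standardize <- function(fit) {
  stopifnot(inherits(fit, "fitted_sur"))
  if (!fit$converged) {
    stop("fit did not converge; refusing to standardise")
  }
  tr <- treatment_effects(fit)
  strata <- fit$design$strata
  # arms need >= 2 observed values each at every occasion
  for (k in seq_along(fit$specs)) {
    tab <- table(fit$design$arm[!is.na(fit$design$Y[, k])])
    if (length(tab) < 2 || any(tab < 2)) {
      stop("occasion '", tr$label[k],
           "': need at least 2 observed outcomes per arm")
    }
  }
  standardize_core(tr$beta, attr(tr, "cov"), tr$time, tr$label,
                   fit$design$Y, fit$design$arm, strata,
                   baseline_time = min(vapply(fit$specs, `[[`, 0,
                                              "baseline_time")))
}

# Trapezium weights: integrating the piecewise-linear interpolant of d(t)
# over [t_1, t_K] is the linear combination sum_k w_k d_k with
# w_1 = (t_2 - t_1)/2, w_K = (t_K - t_{K-1})/2, interior
# w_k = (t_{k+1} - t_{k-1})/2. The weights sum to the span.
trapezium_weights <- function(times) {
  K <- length(times)
  stopifnot(K >= 2)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("occasion times must be strictly increasing")
  }
  w <- numeric(K)
  w[1] <- (times[2] - times[1]) / 2
  w[K] <- (times[K] - times[K - 1]) / 2
  if (K > 2) {
    for (k in 2:(K - 1)) w[k] <- (times[k + 1] - times[k - 1]) / 2
  }
  w
}

#' Area between the arm trajectories, with Wald test
#'
#' Combines the anchored standardised effects into the trapezium-rule area
#' between the treatment and control effect curves over follow-up, a linear
#' combination `w'd` of the occasion effects. Its variance is `w' Cov(d) w`
#' from the joint coefficient covariance (within-group SDs treated as fixed),
#' giving a Wald z and two-sided p. The area divided by the time span is a
#' time-averaged effect size on the Cohen's d scale, the headline scalar.
#'
#' @param traj an [standardize()] trajectory.
#' @return object of class `area_result`: `area` (ES x months), `span`,
#'   `averaged_es`, `se_area`, `z`, `p`, and the per-occasion `weights`.
#' @export
area_between_curves <- function(traj) {
  stopifnot(inherits(traj, "effect_trajectory"))
  times <- traj$time
  w <- trapezium_weights(times)
  C <- attr(traj, "cov")
  area <- sum(w * traj$d)
  v <- drop(t(w) %*% C %*% w)
  if (!is.finite(v) || v < 0) {
    stop("singular or invalid covariance for the area statistic")
  }
  if (v == 0) {
    stop("area statistic has zero variance; covariance is degenerate")
  }
  span <- times[length(times)] - times[1]
  se <- sqrt(v)
  z <- area / se
  structure(list(area = area, span = span, averaged_es = area / span,
                 se_area = se, z = z, p = 2 * pnorm(-abs(z)),
                 weights = setNames(w, traj$label),
                 times = times, d = traj$d),
            class = "area_result")
}

#' @export
print.area_result <- function(x, ...) {
  dir <- if (x$averaged_es < 0) "reduction (benefit on severity scales)"
         else "increase"
  cat(sprintf("Area between curves: %.3f ES x months over %g months\n",
              x$area, x$span))
  cat(sprintf("  time-averaged ES = %.3f (|ES| = %.2f, %s)\n",
              x$averaged_es, abs(x$averaged_es), dir))
  cat(sprintf("  Wald z = %.3f, two-sided p = %.4f\n", x$z, x$p))
  invisible(x)
}

#' Case-wise leave-one-out sensitivity of the area
#'
#' Refits the whole pipeline omitting one participant at a time and records
#' each reduced-data area, flagging whether the full-data result is driven by
#' outliers or a small subset of cases.
#'
#' @param dataset wide trial table.
#' @param specs list of [occasion_spec()]s.
#' @param ... passed to [fit_sur()].
#' @return data.frame with one row per omitted participant (`participant_id`,
#'   `area`, `averaged_es`, `converged`); the full-data area and the maximum
#'   absolute deviation from it are attached as attributes `"full_area"` and
#'   `"max_abs_dev"`.
#' @export
leave_one_out_areas <- function(dataset, specs, ...) {
  full <- area_between_curves(standardize(fit_sur(dataset, specs, ...)))
  ids <- dataset$participant_id
  out <- data.frame(participant_id = ids, area = NA_real_,
                    averaged_es = NA_real_, converged = FALSE)
  for (i in seq_along(ids)) {
    res <- tryCatch({
      f <- suppressWarnings(fit_sur(dataset[-i, , drop = FALSE], specs, ...))
      if (!f$converged) NULL else area_between_curves(standardize(f))
    }, error = function(e) NULL)
    if (!is.null(res)) {
      out$area[i] <- res$area
      out$averaged_es[i] <- res$averaged_es
      out$converged[i] <- TRUE
    }
  }
  attr(out, "full_area") <- full$area
  attr(out, "max_abs_dev") <- max(abs(out$area - full$area), na.rm = TRUE)
  out
}
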