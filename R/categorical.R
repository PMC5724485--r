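#' Freeman-Halton exact test for a 2 x K contingency table
#'
#' Exact conditional test of homogeneity for a two-arm trial against an
#' ordered (or unordered) K-level outcome: conditioning on both margins,
#' every 2 x K table with the observed margins is enumerated, and the
#' p-value is the total hypergeometric-product probability of tables no more
#' probable than the observed one (the r x c generalisation of Fisher's
#' exact test).
#'
#' @param table 2 x K matrix of nonnegative integer counts (rows = arms,
#'   columns = ordered outcome categories).
#' @param tie_tol tables with probability up to `observed + tie_tol` count as
#'   "as extreme" (guards floating-point ties).
#' @return the exact p-value, in (0, 1].
#' @examples
#' fisher_freeman_halton(rbind(c(16, 8, 2), c(16, 7, 4)))
#' @export
fisher_freeman_halton <- function(table, tie_tol = 1e-12) {
  table <- as.matrix(table)
  if (nrow(table) != 2 || ncol(table) < 2) {
    stop("need a 2 x K table with K >= 2")
  }
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be nonnegative integers")
  }
  N <- sum(table)
  if (N == 0) stop("table is empty")
  if (N > 500) {
    stop("margin total ", N, " exceeds the exact-enumeration guard (500); ",
         "a Monte-Carlo mode is not provided")
  }
  csum <- colSums(table)
  r1 <- sum(table[1, ])
  K <- ncol(table)
  lchoose_tab <- function(a) sum(lchoose(csum, a)) - lchoose(N, r1)
  p_obs <- exp(lchoose_tab(table[1, ]))

  # enumerate first-row vectors a with 0 <= a_j <= c_j and sum a = r1
  total <- 0
  a <- integer(K)
  recurse <- function(j, remaining) {
    if (j == K) {
      if (remaining >= 0 && remaining <= csum[K]) {
        a[K] <<- remaining
        p <- exp(lchoose_tab(a))
        if (p <= p_obs + tie_tol) total <<- total + p
      }
      return(invisible())
    }
    lo <- max(0L, remaining - sum(csum[(j + 1):K]))
    hi <- min(csum[j], remaining)
    if (lo > hi) return(invisible())
    for (v in lo:hi) {
      a[j] <<- v
      recurse(j + 1L, remaining - v)
    }
  }
  recurse(1L, r1)
  min(1, total)
}

#' Proportional-odds (cumulative logit) ordinal regression
#'
#' Fits `logit P(Y <= j | x) = theta_j - beta x` by Newton-Raphson (analytic
#' gradient, observed information by central differences, step-halving) and
#' reports the odds ratio `exp(beta)` with Wald standard error and two-sided
#' p-value. `exp(beta)` is the common odds, across every cumulative split of
#' the ordered outcome, of being in a *higher* (more severe) category per
#' unit of `x`.
#'
#' @param outcome ordered factor (or integer codes) of the K-level outcome.
#' @param x numeric covariate; for the trial contrast, an indicator that is
#'   1 for the no-intervention arm (flip it to invert the odds ratio).
#' @param weights optional nonnegative case weights (counts).
#' @return list: `or`, `beta`, `se`, `z`, `p`, `theta` (cutpoints),
#'   `loglik`, `converged`.
#' @export
proportional_odds <- function(outcome, x, weights = NULL) {
  if (is.ordered(outcome) || is.factor(outcome)) {
    y <- as.integer(outcome)
  } else {
    y <- as.integer(factor(outcome))
  }
  stopifnot(length(y) == length(x))
  if (is.null(weights)) weights <- rep(1, length(y))
  keep <- weights > 0
  y <- y[keep]; x <- as.numeric(x[keep]); w <- weights[keep]
  J <- max(y)
  if (J < 2) stop("outcome must have at least 2 observed levels")
  if (length(unique(x)) < 2) stop("covariate x is constant")

  nll <- function(par) {
    theta <- par[1:(J - 1)]; beta <- par[J]
    if (is.unsorted(theta, strictly = TRUE)) return(Inf)
    g <- cbind(0, plogis(outer(-beta * x, theta, `+`)), 1)
    pi <- g[cbind(seq_along(y), y + 1L)] - g[cbind(seq_along(y), y)]
    if (any(pi <= 0)) return(Inf)
    -sum(w * log(pi))
  }
  grad <- function(par) {
    theta <- par[1:(J - 1)]; beta <- par[J]
    eta <- outer(-beta * x, theta, `+`)
    g <- cbind(0, plogis(eta), 1)
    gp <- cbind(0, plogis(eta) * (1 - plogis(eta)), 1e-300 * 0)
    pi <- g[cbind(seq_along(y), y + 1L)] - g[cbind(seq_along(y), y)]
    gu <- gp[cbind(seq_along(y), y + 1L)]
    gl <- gp[cbind(seq_along(y), y)]
    out <- numeric(J)
    for (j in 1:(J - 1)) {
      dj <- (gu * (y == j) - gl * (y - 1L == j)) / pi
      out[j] <- -sum(w * dj)
    }
    out[J] <- -sum(w * (-x) * (gu - gl) / pi)
    out
  }
  # start: empirical cumulative logits, beta = 0
  cw <- vapply(1:(J - 1), function(j) sum(w[y <= j]), 0) / sum(w)
  par <- c(qlogis(pmin(pmax(cw, 1e-4), 1 - 1e-4)), 0)
  ll <- -nll(par)
  converged <- FALSE
  for (it in 1:100) {
    gr <- grad(par)
    H <- numeric_hessian(grad, par)
    step <- tryCatch(solve(H, gr), error = function(e) gr)
    lam <- 1
    repeat {
      cand <- par - lam * step
      llc <- -nll(cand)
      if (is.finite(llc) && llc >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { cand <- par; llc <- ll; break }
    }
    par <- cand
    if (abs(par[J]) > 30) {
      stop("proportional-odds fit diverged; the data show complete ",
           "separation between the covariate and the ordered outcome")
    }
    done <- abs(llc - ll) < 1e-12 * (abs(ll) + 1) && max(abs(gr)) < 1e-6
    ll <- llc
    if (done) { converged <- TRUE; break }
  }
  if (!converged && max(abs(grad(par))) > 1e-4) {
    stop("proportional-odds Newton-Raphson failed to converge")
  }
  H <- numeric_hessian(grad, par)
  vc <- tryCatch(solve(H), error = function(e)
    stop("singular information in proportional-odds fit"))
  beta <- par[J]
  se <- sqrt(vc[J, J])
  z <- beta / se
  list(or = exp(beta), beta = beta, se = se, z = z,
       p = 2 * pnorm(-abs(z)), theta = par[1:(J - 1)], loglik = ll,
       converged = TRUE)
}

# observed information by central differences of the analytic gradient
numeric_hessian <- function(grad, par, h = 1e-6) {
  p <- length(par)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    e <- numeric(p); e[j] <- h * max(1, abs(par[j]))
    H[, j] <- (grad(par + e) - grad(par - e)) / (2 * e[j])
  }
  (H + t(H)) / 2
}

#' Diagnostic-outcome tests for a two-arm trial
#'
#' Convenience wrapper running both categorical analyses on a 2 x K table of
#' ordered diagnostic outcomes: the exact homogeneity test and the
#' proportional-odds odds ratio (covariate = indicator of the
#' no-intervention arm by default; set `indicator_arm = "intervention"` to
#' invert).
#'
#' @param table 2 x K count matrix with rownames `intervention` and
#'   `control` (rows in that order if unnamed); columns ordered from least
#'   to most severe.
#' @param indicator_arm which arm the ordinal-model indicator marks with 1.
#' @return list with `fisher_p` and the `proportional_odds` fit.
#' @export
diagnostic_outcome_tests <- function(table,
                                     indicator_arm = c("control",
                                                       "intervention")) {
  indicator_arm <- match.arg(indicator_arm)
  table <- as.matrix(table)
  if (is.null(rownames(table))) {
    rownames(table) <- c("intervention", "control")
  }
  K <- ncol(table)
  y <- rep(rep(seq_len(K), 2), as.vector(t(table)))
  armv <- rep(rownames(table), rowSums(table))
  po <- proportional_odds(y, as.numeric(armv == indicator_arm))
  list(fisher_p = fisher_freeman_halton(table), proportional_odds = po)
}

rating_pairs_check <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (ncol(ratings) != 2) stop("ratings must have exactly 2 columns (coders)")
  if (nrow(ratings) < 3) stop("need at least 3 rated subjects")
  if (anyNA(ratings)) stop("ratings must be complete (no missing cells)")
  if (!is.numeric(ratings)) stop("ratings must be numeric")
  ratings
}

# one- and two-way ANOVA mean squares for an n x k rating table
rating_anova <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  ssw <- sum((m - row_m)^2)
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), msw = ssw / (n * (k - 1)))
}

#' Intraclass correlations for coder reliability
#'
#' `icc_oneway()` is the one-way random-effects single-measures coefficient
#' ICC(1,1) = (MSB - MSW) / (MSB + (k-1) MSW): raters are not crossed with
#' subjects, so rater effects are absorbed into error. `icc_agreement()` is
#' the two-way random-effects absolute-agreement single-measures coefficient
#' ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n), which
#' penalises systematic differences between coders. Both lie in [-1, 1];
#' near-zero between-subject variance yields a value <= 0, not an error.
#'
#' @param ratings n x 2 numeric matrix (or data.frame), one row per subject,
#'   one column per coder; complete, n >= 3.
#' @return the coefficient (numeric scalar).
#' @examples
#' r <- cbind(c(1, 2, 3, 4, 5, 6), c(2, 3, 3, 5, 5, 7))
#' icc_oneway(r); icc_agreement(r)
#' @export
icc_oneway <- function(ratings) {
  m <- rating_pairs_check(ratings)
  a <- rating_anova(m)
  k <- ncol(m)
  if (a$msw == 0 && a$msr == 0) {
    stop("all ratings identical; intraclass correlation undefined")
  }
  (a$msr - a$msw) / (a$msr + (k - 1) * a$msw)
}

#' @rdname icc_oneway
#' @export
icc_agreement <- function(ratings) {
  m <- rating_pairs_check(ratings)
  a <- rating_anova(m)
  n <- nrow(m); k <- ncol(m)
  denom <- a$msr + (k - 1) * a$mse + k * (a$msc - a$mse) / n
  if (denom == 0) {
    stop("all ratings identical; intraclass correlation undefined")
  }
  (a$msr - a$mse) / denom
}
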