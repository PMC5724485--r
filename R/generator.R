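# Run expr with a private RNG stream; the caller's .Random.seed is restored.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Cholesky draw of n x m standard-normal rows with correlation R.
rmvnorm_chol <- function(n, R) {
  L <- chol(R)
  matrix(rnorm(n * ncol(R)), n, ncol(R)) %*% L
}

# Map a latent standard-normal column onto an instrument scale with the
# target control-arm mean/SD. Maps are monotone; rounding granularity follows
# how each instrument is scored in practice.
map_instrument <- function(z, family, mean, sd) {
  switch(family,
    lognormal = {
      # match mean/SD of the underlying continuous lognormal
      s2 <- log(1 + (sd / mean)^2)
      mu <- log(mean) - s2 / 2
      pmax(0, round(exp(mu + sqrt(s2) * z)))
    },
    normal = round(mean + sd * z),
    bounded7 = round(pmin(7, pmax(1, mean + sd * z)), 1),
    proportion = {
      # logistic map; slope from the delta method so SD is approximately met
      round(plogis(qlogis(mean) + sd / (mean * (1 - mean)) * z), 3)
    },
    stop("unknown family: ", family))
}

#' Generate a synthetic two-arm trial dataset
#'
#' Draws one wide-format dataset (one row per participant) under the
#' configured world: correlated latent traits per outcome series, monotone
#' instrument maps, arm-specific standardised effect curves, complete
#' covariates, visit-level missing-at-random dropout, and an ordered
#' three-level diagnostic outcome. The same configuration and seed reproduce
#' the dataset bit-for-bit.
#'
#' @param config a [trial_config()].
#' @param seed optional integer overriding `config$seed`.
#' @return a `data.frame`: `participant_id`, `arm`, covariates, `age_<t>` per
#'   occasion, one column per configured outcome, `ados_module_<t>` at
#'   follow-up occasions, and `diagnosis`.
#' @examples
#' d <- generate_trial(default_trial_config(seed = 7))
#' table(d$arm)
#' @export
generate_trial <- function(config, seed = NULL) {
  validate_trial_config(config)
  if (is.null(seed)) seed <- config$seed
  with_seed(seed, generate_trial_impl(config))
}

generate_trial_impl <- function(cfg) {
  n_int <- cfg$n_per_arm[["intervention"]]
  n_ctl <- cfg$n_per_arm[["control"]]
  n <- n_int + n_ctl
  arm <- rep(c("intervention", "control"), c(n_int, n_ctl))
  times <- cfg$occasion_times
  cov <- cfg$covariates

  d <- data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    arm = arm,
    centre = cov$centre_levels[1 + rbinom(n, 1, 1 - cov$centre_prob)],
    maternal_education = sample.int(length(cov$education_probs), n,
                                    replace = TRUE,
                                    prob = cov$education_probs),
    ethnicity = c("white", "nonwhite")[1 + rbinom(n, 1, cov$ethnicity_prob)],
    stringsAsFactors = FALSE)

  for (t in times) {
    d[[paste0("age_", t)]] <-
      round(t + runif(n, -cov$age_jitter, cov$age_jitter), 1)
  }

  for (s in cfg$series) {
    Z <- rmvnorm_chol(n, s$corr)
    for (j in seq_along(s$columns)) {
      zj <- Z[, j] + ifelse(arm == "intervention", s$effect[j], 0)
      d[[s$columns[j]]] <- map_instrument(zj, s$family[j], s$mean[j], s$sd[j])
    }
  }

  # assessment module at follow-up occasions (age/language based in reality;
  # here a stable per-child draw), used for SD stratification
  follow <- times[times >= 24]
  module <- sample(c(1L, 2L), n, replace = TRUE, prob = cfg$module_probs)
  for (t in follow) d[[paste0("ados_module_", t)]] <- module

  # three-level diagnostic outcome per arm
  diag_lab <- c("typical", "atypical", "ASD")
  d$diagnosis <- NA_character_
  for (a in c("intervention", "control")) {
    idx <- which(arm == a)
    d$diagnosis[idx] <- sample(diag_lab, length(idx), replace = TRUE,
                               prob = cfg$diagnosis_probs[[a]])
  }

  # visit-level MAR dropout given arm x occasion
  outcome_cols <- unlist(lapply(cfg$series, `[[`, "columns"))
  col_time <- unlist(lapply(cfg$series, `[[`, "times"))
  names(col_time) <- outcome_cols
  for (k in seq_along(times)) {
    t <- times[k]
    p_miss <- cfg$missingness[, k]
    miss <- rbinom(n, 1, p_miss[match(arm, rownames(cfg$missingness))]) == 1
    cols_t <- outcome_cols[col_time == t]
    if (any(miss)) {
      for (cc in cols_t) d[[cc]][miss] <- NA
      mt <- paste0("ados_module_", t)
      if (mt %in% names(d)) d[[mt]][miss] <- NA_integer_
    }
  }
  # baseline visits are never fully missing: restore any participant whose
  # baseline outcomes were all blanked (keeps the anchoring occasion usable)
  base_cols <- outcome_cols[col_time == times[1]]
  if (length(base_cols)) {
    all_miss <- rowSums(!is.na(as.matrix(d[base_cols]))) == 0
    if (any(all_miss)) {
      redo <- which(all_miss)
      for (s in cfg$series) {
        j <- which(s$times == times[1])
        for (jj in j) {
          z <- rnorm(length(redo))
          d[[s$columns[jj]]][redo] <-
            map_instrument(z, s$family[jj], s$mean[jj], s$sd[jj])
        }
      }
    }
  }
  validate_trial_data(d, occasion_times = times)
  d
}
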