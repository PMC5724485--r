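#' Configuration for the synthetic two-arm trial generator
#'
#' The generator emulates a two-arm infancy RCT (default 28 intervention / 26
#' control) assessed at 9, 15, 27 and 39 months. Outcomes are organised in
#' *series*: a series is one developmental domain measured over several
#' occasions, possibly on different instruments as the child ages (e.g. an
#' observational symptom total in infancy replaced by a structured diagnostic
#' total at follow-up). Within a series, a latent standard-normal trait with a
#' cross-occasion correlation matrix drives all occasions; each occasion's
#' latent value is mapped monotonically onto the instrument scale so that the
#' control arm matches the configured mean/SD, and the intervention arm is
#' shifted on the latent scale by the configured standardised effect.
#'
#' @param n_per_arm named integer vector `c(intervention=, control=)`.
#' @param occasion_times assessment ages in months, strictly increasing.
#' @param series named list of series definitions; see [trial_series()].
#' @param missingness 2 x length(occasion_times) matrix of visit-missingness
#'   probabilities, rows named `intervention`/`control`. A missed visit blanks
#'   all outcome columns at that occasion (missing at random given arm and
#'   occasion). Baseline outcomes are never left fully missing for any
#'   participant.
#' @param diagnosis_probs list with per-arm probabilities over the ordered
#'   categories typical < atypical < ASD.
#' @param covariates list: `centre_levels`, `centre_prob` (probability of the
#'   first level), `ethnicity_prob` (probability of "nonwhite"),
#'   `education_probs` (ordinal qualification bands), `age_jitter` months of
#'   uniform jitter around the nominal occasion age.
#' @param module_probs probabilities of structured-assessment module 1 vs 2 at
#'   follow-up (used for SD stratification at the last occasion).
#' @param seed integer seed stored with the configuration.
#' @return an object of class `trial_config`.
#' @seealso [generate_trial()], [default_trial_config()]
#' @export
trial_config <- function(n_per_arm = c(intervention = 28L, control = 26L),
                         occasion_times = c(9, 15, 27, 39),
                         series = default_series(),
                         missingness = default_missingness(),
                         diagnosis_probs = list(
                           control = c(16, 8, 2) / 26,
                           intervention = c(16, 7, 4) / 27),
                         covariates = list(
                           centre_levels = c("site_a", "site_b"),
                           centre_prob = 0.5,
                           ethnicity_prob = 0.15,
                           education_probs = c(0.1, 0.3, 0.4, 0.2),
                           age_jitter = 1.5),
                         module_probs = c(0.5, 0.5),
                         seed = 1L) {
  cfg <- structure(list(
    n_per_arm = n_per_arm, occasion_times = occasion_times, series = series,
    missingness = missingness, diagnosis_probs = diagnosis_probs,
    covariates = covariates, module_probs = module_probs,
    seed = as.integer(seed)), class = "trial_config")
  validate_trial_config(cfg)
  cfg
}

#' Define one outcome series for the generator
#'
#' @param columns column names, one per measured occasion (instrument_time
#'   naming, e.g. `aosi_9`, `ados_27`).
#' @param times occasion ages (months) for each column; must be a subset of
#'   the configuration's occasion grid. Two columns may share a time when two
#'   instruments overlap at one occasion.
#' @param family marginal instrument family per column (recycled):
#'   `"lognormal"` (count-like nonnegative symptom totals, right-skewed,
#'   rounded to integers), `"normal"` (age-normed scores, rounded to
#'   integers), `"bounded7"` (global interaction ratings clipped to 1..7,
#'   1 decimal), `"proportion"` (event-coded proportions in [0,1] via a
#'   logistic map, 3 decimals). A series may mix families when the
#'   instrument changes with age.
#' @param mean,sd target control-arm mean and SD per column.
#' @param effect latent-scale standardised treatment effect per column
#'   (intervention minus control, in latent SD units); must be 0 at the
#'   series' earliest time (randomisation).
#' @param corr cross-occasion correlation matrix for the latent trait, or a
#'   single exchangeable correlation (default 0.4).
#' @return a list describing the series.
#' @export
trial_series <- function(columns, times, family, mean, sd, effect,
                         corr = 0.4) {
  m <- length(columns)
  stopifnot(length(times) == m, length(mean) == m, length(sd) == m,
            length(effect) == m)
  if (is.matrix(corr)) {
    R <- corr
  } else {
    R <- matrix(corr, m, m); diag(R) <- 1
  }
  family <- rep_len(family, m)
  ok <- family %in% c("lognormal", "normal", "bounded7", "proportion")
  if (!all(ok)) stop("unknown instrument family: ",
                     paste(unique(family[!ok]), collapse = ", "))
  list(columns = columns, times = times, family = family,
       mean = mean, sd = sd, effect = effect, corr = R)
}

# Series calibrated to the trial's printed per-arm summary table: control-arm
# cell means/SDs for symptoms (AOSI then ADOS-2 totals), caregiver and child
# dyadic interaction (MACI ratings then DCMA proportions), language T-scores
# and adaptive-behaviour standard scores. Default effects follow the reported
# trajectory shapes: symptom benefit maximal at 27 months, a strong early
# caregiver effect that decays, a steady child dyadic effect, and null-ish
# language/adaptive effects.
default_series <- function() {
  list(
    symptoms = trial_series(
      c("aosi_9", "aosi_15", "ados_27", "ados_39"), c(9, 15, 27, 39),
      "lognormal", mean = c(9.08, 7.31, 6.32, 5.13),
      sd = c(5.32, 5.83, 6.79, 5.03), effect = c(0, -0.3, -0.5, -0.3)),
    parent = trial_series(
      c("maci_nondir_9", "maci_nondir_15", "maci_nondir_27",
        "dcma_sync_27", "dcma_sync_39"), c(9, 15, 27, 27, 39),
      c("bounded7", "bounded7", "bounded7", "proportion", "proportion"),
      mean = c(3.73, 3.92, 4.29, 0.46, 0.45),
      sd = c(1.43, 1.32, 1.73, 0.19, 0.10),
      effect = c(0, 0.8, 0.4, 0.1, 0)),
    child = trial_series(
      c("maci_att_9", "maci_att_15", "maci_att_27",
        "dcma_init_27", "dcma_init_39"), c(9, 15, 27, 27, 39),
      c("bounded7", "bounded7", "bounded7", "proportion", "proportion"),
      mean = c(3.65, 4.19, 4.21, 0.47, 0.44),
      sd = c(1.29, 1.13, 1.44, 0.20, 0.14),
      effect = c(0, 0.35, 0.35, 0.35, 0.35)),
    receptive = trial_series(
      c("mullen_rl_9", "mullen_rl_15", "mullen_rl_27", "mullen_rl_39"),
      c(9, 15, 27, 39), "normal",
      mean = c(50.38, 43.04, 48.92, 50.75), sd = c(9.30, 12.11, 13.68, 13.59),
      effect = c(0, -0.55, 0.1, 0)),
    expressive = trial_series(
      c("mullen_el_9", "mullen_el_15", "mullen_el_27", "mullen_el_39"),
      c(9, 15, 27, 39), "normal",
      mean = c(55.04, 49.77, 47.36, 50.88), sd = c(9.99, 11.13, 13.96, 12.35),
      effect = c(0, -0.3, 0.2, 0)),
    vineland_comm = trial_series(
      c("vabs_comm_9", "vabs_comm_15", "vabs_comm_27", "vabs_comm_39"),
      c(9, 15, 27, 39), "normal",
      mean = c(92.68, 98.76, 99.76, 95.92),
      sd = c(16.18, 14.74, 16.29, 16.47), effect = c(0, -0.35, 0.05, 0.15)),
    vineland_soc = trial_series(
      c("vabs_soc_9", "vabs_soc_15", "vabs_soc_27", "vabs_soc_39"),
      c(9, 15, 27, 39), "normal",
      mean = c(99.92, 97.76, 98.28, 94.54),
      sd = c(10.33, 13.11, 15.78, 13.73), effect = c(0, 0.35, 0.1, 0.1))
  )
}

# Visit-missingness probabilities per arm x occasion, chosen to match the
# printed per-cell Ns (control 26: ~25 at 27 months, ~24 at 39 months;
# intervention 28: ~27 at 15 and 39 months, ~23 at 27 months).
default_missingness <- function() {
  m <- rbind(intervention = c(0, 0.035, 0.18, 0.035),
             control = c(0, 0, 0.05, 0.08))
  colnames(m) <- c("9", "15", "27", "39")
  m
}

#' Default generator configuration, optionally with overridden effect curves
#'
#' @param effects optional named list; each entry replaces the standardised
#'   effect vector of the series of the same name (use `null_effects()` via
#'   `effects = "null"` to zero every series).
#' @param n_per_arm,seed passed to [trial_config()].
#' @return a `trial_config`.
#' @export
default_trial_config <- function(effects = NULL,
                                 n_per_arm = c(intervention = 28L,
                                               control = 26L),
                                 seed = 1L) {
  series <- default_series()
  if (identical(effects, "null")) {
    effects <- lapply(series, function(s) rep(0, length(s$effect)))
  }
  if (!is.null(effects)) {
    for (nm in names(effects)) {
      if (!nm %in% names(series)) stop("unknown series: ", nm)
      stopifnot(length(effects[[nm]]) == length(series[[nm]]$effect))
      series[[nm]]$effect <- effects[[nm]]
    }
  }
  trial_config(n_per_arm = n_per_arm, series = series, seed = seed)
}

validate_trial_config <- function(cfg) {
  problems <- character()
  if (any(cfg$n_per_arm < 1)) problems <- c(problems, "n_per_arm must be >= 1")
  if (is.unsorted(cfg$occasion_times, strictly = TRUE))
    problems <- c(problems, "occasion_times must be strictly increasing")
  for (nm in names(cfg$series)) {
    s <- cfg$series[[nm]]
    R <- s$corr
    if (!isTRUE(all.equal(R, t(R), tolerance = 1e-10)))
      problems <- c(problems,
                    sprintf("series '%s': correlation matrix not symmetric", nm))
    else if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10)
      problems <- c(problems,
                    sprintf("series '%s': correlation matrix not positive-definite", nm))
    if (abs(s$effect[which.min(s$times)]) > 0)
      problems <- c(problems,
                    sprintf("series '%s': effect must be 0 at its baseline occasion", nm))
    if (!all(s$times %in% cfg$occasion_times))
      problems <- c(problems,
                    sprintf("series '%s': times outside the occasion grid", nm))
    if (any(s$sd <= 0))
      problems <- c(problems, sprintf("series '%s': sd must be > 0", nm))
  }
  if (any(cfg$missingness < 0 | cfg$missingness > 1))
    problems <- c(problems, "missingness probabilities must be in [0, 1]")
  for (arm in names(cfg$diagnosis_probs)) {
    p <- cfg$diagnosis_probs[[arm]]
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
      problems <- c(problems,
                    sprintf("diagnosis probabilities for '%s' must be nonnegative and sum to 1", arm))
  }
  if (length(problems)) {
    stop("invalid trial_config:\n  - ", paste(problems, collapse = "\n  - "))
  }
  invisible(cfg)
}
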