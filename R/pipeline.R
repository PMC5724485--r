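#' Default analysis blocks for the generated trial schema
#'
#' One block per prespecified outcome domain, each a list of
#' [occasion_spec()]s covering the post-baseline occasions: autism symptom
#' severity (observational total in infancy, log-transformed structured
#' total at follow-up, SD-stratified by module at the last occasion),
#' caregiver and child dyadic interaction (global ratings switching to
#' event-coded proportions), receptive/expressive language T-scores and
#' adaptive-behaviour standard scores. Every equation adjusts for the
#' relevant baseline measure, centre, age-at-assessment, maternal ethnicity
#' and maternal education.
#'
#' @return named list of blocks (each a list of `occasion_spec`s).
#' @export
default_analysis_blocks <- function() {
  covs <- function(t) c("centre", paste0("age_", t), "ethnicity",
                        "maternal_education")
  blk <- function(specs) specs
  spec <- function(label, t, outcome, baseline, transform = "identity",
                   stratum = NULL) {
    occasion_spec(label, t, outcome, transform = transform,
                  baseline_column = baseline, baseline_time = 9,
                  covariate_columns = covs(t),
                  sd_stratum_column = stratum)
  }
  list(
    symptoms = blk(list(
      spec("15m", 15, "aosi_15", "aosi_9"),
      spec("27m", 27, "ados_27", "aosi_9", transform = "log1p"),
      spec("39m", 39, "ados_39", "aosi_9", transform = "log1p",
           stratum = "ados_module_39"))),
    parent_dyadic = blk(list(
      spec("15m", 15, "maci_nondir_15", "maci_nondir_9"),
      spec("27m", 27, "maci_nondir_27", "maci_nondir_9"),
      spec("39m", 39, "dcma_sync_39", "maci_nondir_9"))),
    child_dyadic = blk(list(
      spec("15m", 15, "maci_att_15", "maci_att_9"),
      spec("27m", 27, "maci_att_27", "maci_att_9"),
      spec("39m", 39, "dcma_init_39", "maci_att_9"))),
    receptive_language = blk(list(
      spec("15m", 15, "mullen_rl_15", "mullen_rl_9"),
      spec("27m", 27, "mullen_rl_27", "mullen_rl_9"),
      spec("39m", 39, "mullen_rl_39", "mullen_rl_9"))),
    expressive_language = blk(list(
      spec("15m", 15, "mullen_el_15", "mullen_el_9"),
      spec("27m", 27, "mullen_el_27", "mullen_el_9"),
      spec("39m", 39, "mullen_el_39", "mullen_el_9"))),
    adaptive_communication = blk(list(
      spec("15m", 15, "vabs_comm_15", "vabs_comm_9"),
      spec("27m", 27, "vabs_comm_27", "vabs_comm_9"),
      spec("39m", 39, "vabs_comm_39", "vabs_comm_9"))),
    adaptive_socialisation = blk(list(
      spec("15m", 15, "vabs_soc_15", "vabs_soc_9"),
      spec("27m", 27, "vabs_soc_27", "vabs_soc_9"),
      spec("39m", 39, "vabs_soc_39", "vabs_soc_9")))
  )
}

#' Assemble an end-to-end analysis configuration
#'
#' @param dataset a trial data.frame or a CSV path readable by
#'   [read_trial()].
#' @param blocks named list of spec lists; defaults to
#'   [default_analysis_blocks()].
#' @param bootstrap_B bootstrap replicates per block (0 disables).
#' @param level confidence level.
#' @param seed integer seed for the bootstrap streams.
#' @param out_dir output directory for the report bundle (`NULL` = no files).
#' @param plots write SVG trajectory plots (requires cairo support).
#' @param bonferroni also report Bonferroni-adjusted p-values across blocks
#'   (off by default; the blocks are prespecified outcomes).
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(dataset, blocks = default_analysis_blocks(),
                            bootstrap_B = 1000, level = 0.95, seed = 1L,
                            out_dir = NULL, plots = TRUE,
                            bonferroni = FALSE) {
  structure(list(dataset = dataset, blocks = blocks,
                 bootstrap_B = bootstrap_B, level = level,
                 seed = as.integer(seed), out_dir = out_dir, plots = plots,
                 bonferroni = bonferroni),
            class = "analysis_config")
}

validate_analysis_config <- function(config, dataset) {
  problems <- character()
  for (bn in names(config$blocks)) {
    specs <- config$blocks[[bn]]
    times <- vapply(specs, `[[`, 0, "time")
    if (is.unsorted(times, strictly = TRUE)) {
      problems <- c(problems,
                    sprintf("block '%s': occasion times must be strictly increasing", bn))
    }
    for (s in specs) {
      need <- c(s$outcome_column, s$baseline_column, s$covariate_columns,
                s$treatment_column, s$sd_stratum_column)
      miss <- setdiff(need, names(dataset))
      if (length(miss)) {
        problems <- c(problems,
                      sprintf("block '%s', occasion '%s': missing columns: %s",
                              bn, s$label, paste(miss, collapse = ", ")))
      }
    }
  }
  if (length(problems)) {
    stop("invalid analysis config:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  invisible(TRUE)
}

#' Run the full trajectory-area pipeline
#'
#' For each configured domain block: joint ML fit of the occasion
#' regressions, Cohen's d standardisation, trapezium area with Wald test,
#' and (optionally) the participant bootstrap. A failing block is recorded
#' and flagged; it does not abort the other blocks. When `out_dir` is set,
#' writes `summary.json`, a human-readable `report.md`, one trajectory CSV
#' per block and (optionally) SVG profile plots. Reruns with the same
#' configuration and seed regenerate identical reports.
#'
#' @param config an [analysis_config()].
#' @return (invisibly) a named list of per-block results: `fit`, `trajectory`,
#'   `area`, `bootstrap` (or `error`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dataset <- config$dataset
  if (is.character(dataset)) dataset <- read_trial(dataset)
  validate_analysis_config(config, dataset)

  results <- list()
  for (bn in names(config$blocks)) {
    specs <- config$blocks[[bn]]
    results[[bn]] <- tryCatch({
      fit <- suppressWarnings(fit_sur(dataset, specs))
      traj <- standardize(fit)
      area <- area_between_curves(traj)
      boot <- NULL
      if (config$bootstrap_B > 0) {
        boot <- suppressWarnings(bootstrap_area(
          dataset, specs, B = config$bootstrap_B, level = config$level,
          seed = config$seed + match(bn, names(config$blocks)),
          force = TRUE))
      }
      list(fit = fit, trajectory = traj, area = area, bootstrap = boot)
    }, error = function(e) list(error = conditionMessage(e)))
  }
  if (!is.null(config$out_dir)) {
    write_report_bundle(results, config, dataset)
  }
  invisible(results)
}

block_summary <- function(results, config) {
  p_raw <- vapply(results, function(r)
    if (is.null(r$error)) r$area$p else NA_real_, 0)
  p_adj <- if (config$bonferroni) pmin(1, p_raw * sum(!is.na(p_raw))) else NULL
  out <- list()
  for (bn in names(results)) {
    r <- results[[bn]]
    if (!is.null(r$error)) {
      out[[bn]] <- list(failed = TRUE, error = r$error)
      next
    }
    s <- list(
      failed = FALSE,
      occasions = r$trajectory[c("label", "time", "d", "se", "sd_within",
                                 "beta")],
      area = r$area$area, span = r$area$span,
      averaged_es = r$area$averaged_es, se_area = r$area$se_area,
      wald_z = r$area$z, p = r$area$p,
      weights = as.list(r$area$weights),
      n_used = r$fit$n_used, n_dropped = r$fit$n_dropped,
      loglik = r$fit$loglik, converged = r$fit$converged)
    if (!is.null(p_adj)) s$p_bonferroni <- unname(p_adj[match(bn,
                                                      names(results))])
    if (!is.null(r$bootstrap)) {
      s$bootstrap <- list(level = r$bootstrap$level,
                          ci_averaged = r$bootstrap$ci_averaged,
                          ci_area = r$bootstrap$ci_area,
                          n_requested = r$bootstrap$n_requested,
                          n_converged = r$bootstrap$n_converged,
                          seed = r$bootstrap$seed)
    }
    out[[bn]] <- s
  }
  out
}

write_report_bundle <- function(results, config, dataset) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  summ <- list(seed = config$seed, n = nrow(dataset),
               arms = as.list(table(dataset$arm)),
               blocks = block_summary(results, config))
  jsonlite::write_json(summ, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  lines <- c("# Trajectory-area analysis report", "",
             sprintf("Participants: %d (%s)", nrow(dataset),
                     paste(sprintf("%s %d", names(table(dataset$arm)),
                                   table(dataset$arm)), collapse = ", ")),
             sprintf("Seed: %d", config$seed), "")
  for (bn in names(results)) {
    r <- results[[bn]]
    lines <- c(lines, sprintf("## %s", bn), "")
    if (!is.null(r$error)) {
      lines <- c(lines, sprintf("**FAILED**: %s", r$error), "")
      next
    }
    utils::write.csv(r$trajectory,
                     file.path(config$out_dir,
                               paste0("trajectory_", bn, ".csv")),
                     row.names = FALSE)
    dirword <- if (r$area$averaged_es < 0) "in favour of intervention on a severity scale"
               else "towards higher scores under intervention"
    lines <- c(lines,
               sprintf("- time-averaged ES |%.2f| (%s), area %.2f ES-months over %g months",
                       abs(r$area$averaged_es), dirword, r$area$area,
                       r$area$span),
               sprintf("- Wald z = %.2f, p = %.3f", r$area$z, r$area$p))
    if (!is.null(r$bootstrap)) {
      lines <- c(lines,
                 sprintf("- %d%% bootstrap CI for averaged ES: [%.2f, %.2f] (%d/%d replicates)",
                         round(100 * r$bootstrap$level),
                         r$bootstrap$ci_averaged[1],
                         r$bootstrap$ci_averaged[2],
                         r$bootstrap$n_converged, r$bootstrap$n_requested))
    }
    lines <- c(lines, "")
    if (config$plots && capabilities("cairo")) {
      svg_path <- file.path(config$out_dir, paste0("profile_", bn, ".svg"))
      tryCatch({
        grDevices::svg(svg_path, width = 6, height = 4)
        plot_trajectory(r$trajectory, main = bn)
        grDevices::dev.off()
      }, error = function(e) try(grDevices::dev.off(), silent = TRUE))
    }
  }
  writeLines(lines, file.path(config$out_dir, "report.md"))
  invisible(config$out_dir)
}

#' Plot a standardised effect trajectory
#'
#' Point estimates with normal-theory whiskers at each occasion, joined by
#' the piecewise-linear curve whose integral is the reported area; the
#' control arm is the zero reference line.
#'
#' @param traj an `effect_trajectory`.
#' @param main plot title.
#' @export
plot_trajectory <- function(traj, main = "treatment effect trajectory") {
  lo <- traj$d - 1.96 * traj$se
  hi <- traj$d + 1.96 * traj$se
  graphics::plot(traj$time, traj$d, type = "b", pch = 19,
                 ylim = range(lo, hi, 0), xlab = "age (months)",
                 ylab = "standardised effect (Cohen's d)", main = main)
  graphics::abline(h = 0, lty = 2, col = "grey40")
  graphics::arrows(traj$time, lo, traj$time, hi, angle = 90, code = 3,
                   length = 0.04)
  invisible(traj)
}
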