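# Known column families and their admissible ranges. Outcome columns follow
# the instrument_time naming convention (e.g. aosi_9, ados_27, maci_att_15,
# dcma_sync_39); anything else passes through unchecked.
column_range <- function(name) {
  if (grepl("^(aosi|ados)_[0-9]+$", name)) return(c(0, Inf))
  if (grepl("^maci_", name)) return(c(1, 7))
  if (grepl("^dcma_", name)) return(c(0, 1))
  NULL
}

#' Validate a wide-format trial table
#'
#' Checks the schema invariants: required identifier/arm columns, unique
#' participant ids, admissible arm and diagnosis labels, instrument ranges
#' (MACI in 1..7, DCMA in 0..1, symptom totals nonnegative), strictly
#' increasing ages across occasions, and at least one observed baseline
#' outcome per participant. All violations are collected and reported
#' together.
#'
#' @param d data.frame to validate.
#' @param occasion_times occasion grid used for the age columns; inferred
#'   from `age_<t>` columns when `NULL`.
#' @return `d`, invisibly; errors with the full violation list otherwise.
#' @export
validate_trial_data <- function(d, occasion_times = NULL) {
  problems <- character()
  need <- c("participant_id", "arm")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("invalid trial data:\n  - missing required columns: ",
         paste(miss, collapse = ", "))
  }
  if (anyDuplicated(d$participant_id)) {
    dup <- unique(d$participant_id[duplicated(d$participant_id)])
    problems <- c(problems, paste0("duplicate participant_id: ",
                                   paste(dup, collapse = ", ")))
  }
  bad_arm <- setdiff(unique(d$arm), c("intervention", "control"))
  if (length(bad_arm)) {
    problems <- c(problems, paste0("unknown arm labels: ",
                                   paste(bad_arm, collapse = ", ")))
  }
  if ("diagnosis" %in% names(d)) {
    bad <- setdiff(unique(d$diagnosis[!is.na(d$diagnosis)]),
                   c("typical", "atypical", "ASD"))
    if (length(bad)) {
      problems <- c(problems, paste0("unknown diagnosis labels: ",
                                     paste(bad, collapse = ", ")))
    }
  }
  for (nm in names(d)) {
    rng <- column_range(nm)
    if (is.null(rng)) next
    v <- d[[nm]]
    if (!is.numeric(v)) {
      problems <- c(problems, paste0("column ", nm, " must be numeric"))
      next
    }
    out <- which(!is.na(v) & (v < rng[1] | v > rng[2]))
    if (length(out)) {
      problems <- c(problems,
                    sprintf("column %s out of range [%s, %s] at rows: %s",
                            nm, rng[1], rng[2],
                            paste(head(out, 10), collapse = ", ")))
    }
  }
  if (is.null(occasion_times)) {
    age_cols <- grep("^age_[0-9]+$", names(d), value = TRUE)
    occasion_times <- sort(as.numeric(sub("age_", "", age_cols)))
  }
  age_cols <- paste0("age_", occasion_times)
  if (length(age_cols) > 1 && all(age_cols %in% names(d))) {
    ages <- as.matrix(d[age_cols])
    nondec <- which(apply(ages, 1, function(a) any(diff(a) <= 0)))
    if (length(nondec)) {
      problems <- c(problems,
                    paste0("ages not strictly increasing at rows: ",
                           paste(head(nondec, 10), collapse = ", ")))
    }
  }
  if (length(occasion_times)) {
    base_cols <- outcome_columns_at(d, occasion_times[1])
    if (length(base_cols)) {
      all_miss <- which(rowSums(!is.na(as.matrix(d[base_cols]))) == 0)
      if (length(all_miss)) {
        problems <- c(problems,
                      paste0("all baseline outcomes missing at rows: ",
                             paste(head(all_miss, 10), collapse = ", ")))
      }
    }
  }
  if (length(problems)) {
    stop("invalid trial data:\n  - ", paste(problems, collapse = "\n  - "))
  }
  invisible(d)
}

outcome_columns_at <- function(d, t) {
  grep(paste0("^(aosi|ados|maci_[a-z]+|dcma_[a-z]+|mullen_[a-z]+|vabs_[a-z]+)_",
              t, "$"), names(d), value = TRUE)
}

#' Write / read a trial table as CSV
#'
#' Wide format, one row per participant, missing values as empty cells.
#' `read_trial(write_trial(d, f))` reproduces `d` exactly, including the
#' missingness pattern and column order.
#'
#' @param d validated trial data.frame.
#' @param path file path.
#' @return `write_trial` returns `path` invisibly; `read_trial` returns the
#'   validated data.frame.
#' @export
write_trial <- function(d, path) {
  validate_trial_data(d)
  write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  d <- read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                check.names = FALSE)
  # outcome and age columns are double even when every written value was
  # integral, so a round-trip reproduces the in-memory types
  num_pat <- "^(age_|aosi_|ados_[0-9]|maci_|dcma_|mullen_|vabs_)"
  for (nm in grep(num_pat, names(d), value = TRUE)) {
    d[[nm]] <- as.numeric(d[[nm]])
  }
  validate_trial_data(d)
  d
}
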