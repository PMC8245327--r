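trial_columns <- c("trial_id", "group", "min_age", "max_age", "mean_age",
                   "sd_age", "pct_women", "n_participants", "followup_days",
                   "n_sae", "n_endpoint_events", "outcome_type",
                   "drug_class", "comparison_type", "phase", "arm")

#' Read a trial registry from CSV
#'
#' Reads, types and validates trial records. Rows violating hard invariants
#' (nonpositive participants or follow-up, negative counts, inconsistent
#' age bounds) are rejected with row-numbered warnings; rows merely missing
#' the age-sex fields needed for standardisation are kept and marked
#' ineligible (column `standardisation_eligible`), since published reports
#' often omit them.
#'
#' @param path CSV path with a header matching the documented schema (see
#'   [write_trials()]).
#' @return Data frame of trial records.
#' @export
read_trials <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(setdiff(trial_columns, "arm"), names(raw))
  if (length(missing_cols)) {
    stop("trial CSV lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"arm" %in% names(raw)) raw$arm <- NA_character_
  if (nrow(raw) == 0) {
    warning("trial CSV contains a header but no rows", call. = FALSE)
    raw$standardisation_eligible <- logical(0)
    return(raw)
  }
  num_cols <- c("min_age", "max_age", "mean_age", "sd_age", "pct_women",
                "followup_days")
  int_cols <- c("n_participants", "n_sae", "n_endpoint_events", "phase")
  for (cl in num_cols) raw[[cl]] <- as.numeric(raw[[cl]])
  for (cl in int_cols) raw[[cl]] <- as.integer(raw[[cl]])

  dup <- duplicated(raw$trial_id)
  if (any(dup) && !any(!is.na(raw$arm))) {
    stop("duplicate trial_id(s) in trial CSV: ",
         paste(unique(raw$trial_id[dup]), collapse = ", "), call. = FALSE)
  }

  bad_msgs <- character(0)
  ok <- rep(TRUE, nrow(raw))
  flag_bad <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx)) {
      bad_msgs <<- c(bad_msgs, sprintf("row %d: %s", idx, msg))
      ok[idx] <<- FALSE
    }
  }
  flag_bad(is.na(raw$n_participants) | raw$n_participants <= 0,
           "n_participants must be a positive count")
  flag_bad(is.na(raw$followup_days) | raw$followup_days <= 0,
           "followup_days must be positive")
  flag_bad(is.na(raw$n_sae) | raw$n_sae < 0, "n_sae must be >= 0")
  flag_bad(!is.na(raw$min_age) & !is.na(raw$mean_age) &
             raw$min_age >= raw$mean_age,
           "min_age must lie below mean_age")
  flag_bad(!is.na(raw$max_age) & !is.na(raw$mean_age) &
             raw$max_age <= raw$mean_age,
           "max_age must lie above mean_age")
  flag_bad(!raw$group %in% c("older", "standard"),
           "group must be 'older' or 'standard'")
  if (length(bad_msgs)) {
    warning("rejected ", sum(!ok), " trial row(s):\n  ",
            paste(bad_msgs, collapse = "\n  "), call. = FALSE)
  }
  out <- raw[ok, , drop = FALSE]
  rownames(out) <- NULL
  out$standardisation_eligible <- !is.na(out$mean_age) &
    !is.na(out$pct_women)
  out
}

#' Write a trial registry to CSV
#'
#' @param trials Data frame of trial records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  cols <- intersect(trial_columns, names(trials))
  utils::write.csv(trials[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

parse_event_times <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) numeric(0)
    else as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

#' Write / read a community cohort as CSV
#'
#' Event times (day offsets within follow-up) are serialised as a
#' semicolon-separated field so the table stays plain text.
#'
#' @param cohort Cohort data frame (see [generate_cohort()]).
#' @param path CSV path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns
#'   the cohort data frame with `event_times` restored as a list column.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  if (is.list(out$event_times)) {
    out$event_times <- vapply(out$event_times,
                              function(t) paste(sprintf("%.6f", t),
                                                collapse = ";"),
                              character(1))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(event_times = "character"))
  raw$event_times <- parse_event_times(raw$event_times)
  for (f in intersect(c("diabetes", "heart_failure", "ckd"), names(raw))) {
    raw[[f]] <- as.logical(raw[[f]])
  }
  raw
}

#' Read a run configuration file
#'
#' Configurations are flat, commented YAML; unspecified entries fall back
#' to [default_config()] values (recursively merged).
#'
#' @param path YAML file path.
#' @return A full configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}
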