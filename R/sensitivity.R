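#' Leave-one-out sensitivity analysis over trials
#'
#' Re-runs a model fit excluding each trial in turn, tabulating the
#' group-contrast estimate per variant; used to check that no single trial
#' (particularly among the small older-trial group) drives the group
#' contrast.
#'
#' @param trials Data frame of trial records.
#' @param fit_fn Function taking a trials data frame and returning a
#'   `hier_fit`; its first derived contrast is tabulated (or the one named
#'   by `contrast`).
#' @param contrast Name of the derived contrast to extract; defaults to the
#'   first.
#' @param baseline Optional precomputed full-data `hier_fit`; computed if
#'   missing.
#' @return An object of class `sensitivity_report` with one variant per
#'   excluded trial; variants whose refit fails (e.g. a lost covariate
#'   level) are flagged, not fatal.
#' @export
leave_one_out <- function(trials, fit_fn, contrast = NULL,
                          baseline = NULL) {
  stopifnot(nrow(trials) >= 3)
  if (is.null(baseline)) baseline <- fit_fn(trials)
  pick <- function(fit) {
    ct <- fit$contrasts
    nm <- if (is.null(contrast)) ct$name[1] else contrast
    ct[ct$name == nm, , drop = FALSE]
  }
  base_row <- pick(baseline)
  variants <- lapply(seq_len(nrow(trials)), function(i) {
    out <- data.frame(variant = paste0("excl_", trials$trial_id[i]),
                      excluded_trial = trials$trial_id[i],
                      estimate = NA_real_, lo = NA_real_, hi = NA_real_,
                      flagged = FALSE, note = "",
                      stringsAsFactors = FALSE)
    fit <- tryCatch(suppressWarnings(fit_fn(trials[-i, , drop = FALSE])),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      out$flagged <- TRUE
      out$note <- conditionMessage(fit)
      return(out)
    }
    row <- pick(fit)
    out$estimate <- row$median
    out$lo <- row$lo
    out$hi <- row$hi
    if (!isTRUE(fit$converged)) out$note <- "convergence diagnostic high"
    out
  })
  structure(list(analysis_name = "leave_one_out",
                 contrast = base_row$name,
                 baseline = data.frame(estimate = base_row$median,
                                       lo = base_row$lo, hi = base_row$hi),
                 variants = do.call(rbind, variants)),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Sensitivity analysis:", x$analysis_name, "\n")
  if (!is.null(x$contrast)) cat("contrast:", x$contrast, "\n")
  cat(nrow(x$variants), "variants; baseline estimate ",
      format(x$baseline$estimate, digits = 4), "\n")
  invisible(x)
}

#' Restrict the community cohort by condition flags
#'
#' Drops every cohort member with any of the named condition flags set —
#' the misclassification sensitivity analysis (people whose treatment may
#' have been indicated by diabetes, heart failure or chronic kidney disease
#' rather than hypertension alone). The number excluded is logged and
#' attached as attribute `n_excluded`.
#'
#' @param cohort Cohort data frame carrying logical flag columns.
#' @param flags Flag column names; all must be present.
#' @return The cohort subset with all named flags `FALSE`.
#' @export
restrict_cohort <- function(cohort,
                            flags = c("diabetes", "heart_failure", "ckd")) {
  missing_cols <- setdiff(flags, names(cohort))
  if (length(missing_cols)) {
    stop("cohort lacks required flag column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  any_flag <- Reduce(`|`, lapply(flags, function(f) cohort[[f]]))
  out <- cohort[!any_flag, , drop = FALSE]
  rownames(out) <- NULL
  message(sum(any_flag), " of ", nrow(cohort),
          " cohort members excluded by condition flags")
  attr(out, "n_excluded") <- sum(any_flag)
  out
}

#' Truncate cohort follow-up to a window, first event only
#'
#' Matches the community observation window to typical trial follow-up:
#' each person is censored at the first event, the window (default 90
#' days), or their original follow-up end, whichever happens first, and
#' contributes at most one event.
#'
#' @param cohort Cohort with `event_times` (list of event-day offsets per
#'   person, as produced by [generate_cohort()]).
#' @param window_days Truncation window in days.
#' @return Cohort variant with updated `person_years`, `n_events`,
#'   `event_times`.
#' @export
truncate_followup_first_event <- function(cohort, window_days = 90) {
  if (!"event_times" %in% names(cohort)) {
    stop("cohort lacks the event_times column; regenerate the cohort with ",
         "per-event times to run the first-event analysis", call. = FALSE)
  }
  et <- cohort$event_times
  if (is.character(et)) et <- parse_event_times(et)
  orig_days <- cohort$person_years * DAYS_PER_YEAR
  first <- vapply(et, function(t) if (length(t)) t[1] else Inf, numeric(1))
  horizon <- pmin(window_days, orig_days)
  has_event <- first <= horizon
  cens_days <- pmin(first, horizon)
  out <- cohort
  out$person_years <- cens_days / DAYS_PER_YEAR
  out$n_events <- as.integer(has_event)
  out$event_times <- lapply(seq_along(et), function(i) {
    if (has_event[i]) first[i] else numeric(0)
  })
  out
}
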