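#' @keywords internal
#' @importFrom stats update
"_PACKAGE"

# Fixed year length for all day <-> year conversions.
DAYS_PER_YEAR <- 365.25

#' Convert days to years
#'
#' All conversions in the package use a fixed year length of 365.25 days.
#'
#' @param days Numeric vector of durations in days.
#' @return Durations in years.
#' @export
days_to_years <- function(days) days / DAYS_PER_YEAR

# Validation helper: stop with a message naming the offending field.
check_that <- function(cond, field, msg) {
  if (!isTRUE(cond)) {
    stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
  }
  invisible(TRUE)
}

check_scalar_number <- function(x, field, lower = -Inf, upper = Inf,
                                allow_na = FALSE) {
  check_that(length(x) == 1L, field, "must be a single value")
  if (allow_na && is.na(x)) return(invisible(TRUE))
  check_that(is.numeric(x) && is.finite(x), field, "must be a finite number")
  check_that(x >= lower && x <= upper, field,
             sprintf("must be in [%s, %s]", format(lower), format(upper)))
  invisible(TRUE)
}

#' Derive a per-stage random seed from a global seed
#'
#' A completed run is reproducible from a single integer seed: each pipeline
#' stage draws its randomness from a sub-seed obtained by a fixed, documented
#' arithmetic derivation, so stages can be re-run independently and still
#' match an end-to-end run.
#'
#' @param seed Global integer seed.
#' @param stage Stage name, one of the names in `.stage_offsets`.
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  offsets <- c(cohort = 11L, trials = 29L, arms = 47L, rates = 61L,
               eo = 83L, irr = 101L, sr = 127L, sensitivity = 151L,
               oracle = 199L)
  if (!stage %in% names(offsets)) {
    stop("unknown stage: ", stage, call. = FALSE)
  }
  as.integer((as.double(seed) * 1009 + offsets[[stage]]) %% 2147483647)
}

# Observed-count rule: hard-outcome trials pool clinical endpoint events with
# SAEs before any rate or ratio computation; soft-outcome trials use SAEs only.
#' Observed event count for a trial
#'
#' For trials with a hard (clinical-endpoint) outcome, endpoint events are
#' added to the serious adverse event count, since both predominantly
#' represent hospitalisations or deaths. Soft-outcome trials contribute their
#' SAE count alone.
#'
#' @param trials Data frame of trial records.
#' @return Integer vector of observed counts.
#' @export
observed_count <- function(trials) {
  extra <- ifelse(!is.na(trials$outcome_type) & trials$outcome_type == "hard",
                  trials$n_endpoint_events, 0L)
  extra[is.na(extra)] <- 0L
  as.integer(trials$n_sae + extra)
}
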