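#' Estimated person-years of follow-up for a trial
#'
#' Trial reports rarely give person-time directly; it is estimated as
#' `follow-up x (number of participants - 0.5 x number of serious adverse
#' events)`, i.e. participants with an SAE are assumed to contribute, on
#' average, half the follow-up. Follow-up in days is converted to years at
#' 365.25 days/year.
#'
#' @param trials Data frame of trial records with columns `followup_days`,
#'   `n_participants`, `n_sae`.
#' @return Person-years per trial (numeric vector).
#' @export
estimate_person_years <- function(trials) {
  eff_n <- trials$n_participants - 0.5 * trials$n_sae
  if (any(eff_n <= 0)) {
    bad <- which(eff_n <= 0)
    stop("nonpositive exposure for trial(s) ",
         paste(trials$trial_id[bad], collapse = ", "),
         ": n_participants must exceed 0.5 * n_sae", call. = FALSE)
  }
  days_to_years(trials$followup_days) * eff_n
}

#' Discretised age-sex distribution of a trial population
#'
#' Converts fitted truncated-normal age parameters plus the reported sex mix
#' into stratum weights: the truncated-normal mass in each age bin (over the
#' eligibility window clipped to a configured adult support), split between
#' sexes by the fraction of women. Weights are normalised to sum to 1.
#'
#' @param trial One-row data frame (a trial record) providing `pct_women`.
#' @param params A [fit_truncated_normal()] result for the trial's ages.
#' @param bin_width Age bin width in years (default 1).
#' @param support Ages are clipped to this range when eligibility bounds are
#'   absent or wider; default `c(18, 100)` (adult trials, finite support).
#' @return Data frame with columns `age` (bin midpoint), `sex`, `weight`.
#' @export
age_sex_distribution <- function(trial, params, bin_width = 1,
                                 support = c(18, 100)) {
  stopifnot(inherits(params, "truncnorm_params"))
  pw <- trial$pct_women
  if (is.na(pw) || pw < 0 || pw > 1) {
    stop("trial ", trial$trial_id, ": pct_women missing or outside [0, 1]; ",
         "trial is ineligible for standardisation", call. = FALSE)
  }
  lo <- max(params$lower, support[1])
  hi <- min(params$upper, support[2])
  stopifnot(lo < hi)
  edges <- seq(lo, hi, by = bin_width)
  if (edges[length(edges)] < hi) edges <- c(edges, hi)
  mass <- diff(stats::pnorm(edges, params$mu, params$sigma))
  if (sum(mass) <= 0) {
    stop("age distribution carries no mass on [", lo, ", ", hi, "]",
         call. = FALSE)
  }
  mass <- mass / sum(mass)
  mids <- (edges[-length(edges)] + edges[-1]) / 2
  data.frame(age = rep(mids, 2),
             sex = rep(c("female", "male"), each = length(mids)),
             weight = c(mass * pw, mass * (1 - pw)))
}

#' Expected event count for a trial under the community rate model
#'
#' Indirect standardisation: the community age-sex-specific rates are applied
#' to the trial's reconstructed age-sex distribution, and the resulting
#' average rate is multiplied by the trial's estimated person-years. The
#' trial's person-time is split across strata proportionally to the age-sex
#' weights (exchangeable follow-up).
#'
#' @param trial One-row trial record.
#' @param dist An [age_sex_distribution()] for the trial.
#' @param model A [rate_model()].
#' @return Expected number of events (strictly positive scalar).
#' @export
expected_count <- function(trial, dist, model) {
  py <- estimate_person_years(trial)
  rates <- predict_rate(model, dist$age, dist$sex)
  py * sum(dist$weight * rates)
}

# Strata-level expected counts for a matrix of coefficient draws:
# returns a vector of expected counts, one per draw. Draws are processed
# in blocks so very large reruns stay within a few tens of MB.
expected_count_draws <- function(py, dist, covariate_spec, coef_draws,
                                 block = 20000L) {
  S <- rate_design(covariate_spec, dist$age, dist$sex)
  n <- nrow(coef_draws)
  out <- numeric(n)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    R <- exp(S %*% t(coef_draws[idx, , drop = FALSE]))
    out[idx] <- drop(crossprod(dist$weight, R))
  }
  py * out
}

# Zero-truncated Poisson draws: rpois with zeros redrawn. An untruncated
# denominator would make the ratio's mean infinite in expectation.
rztpois <- function(n, lambda) {
  x <- stats::rpois(n, lambda)
  while (any(x == 0L)) {
    i <- which(x == 0L)
    x[i] <- stats::rpois(length(i), lambda)
  }
  x
}

#' Monte Carlo expected-to-observed ratio for one trial
#'
#' Propagates both sources of uncertainty in the per-trial ratio of
#' community-expected events to trial-observed events: `n_samples`
#' coefficient vectors are drawn from the rate model's multivariate normal
#' sampling distribution and mapped to expected counts through the trial's
#' age-sex distribution, and `n_samples` observed-count values are drawn
#' from a Poisson distribution whose parameter is the observed count (zero
#' draws redrawn, i.e. a zero-truncated denominator). The two streams are
#' divided pairwise (default) and summarised by the mean and the 2.5th and
#' 97.5th centiles.
#'
#' Trials with zero observed events get status `excluded_zero_events` (the
#' ratio would be infinite); trials with exactly one observed event are
#' computed but flagged `unstable_low_events` (their ratios are typically
#' huge and are excluded from forest-style displays).
#'
#' @param trial One-row trial record.
#' @param model A [rate_model()].
#' @param n_samples Number of Monte Carlo draws (default 10000).
#' @param seed Integer seed.
#' @param default_sd Underlying-normal age scale when the trial reports no
#'   age SD (years).
#' @param bin_width Age bin width for the discretised distribution.
#' @param support Adult age support used to clip missing bounds.
#' @param pairing `"paired"` divides the two draw vectors elementwise;
#'   `"cross"` uses the full cross product of numerator and denominator
#'   draws (summaries estimated from up to 1e6 random pairs).
#' @return One-row data frame (an E/O ratio summary): `trial_id`, `group`,
#'   `expected_count`, `observed_count`, `ratio_mean`, `ratio_lo`,
#'   `ratio_hi`, `n_samples`, `seed`, `status`.
#' @export
eo_ratio_mc <- function(trial, model, n_samples = 10000, seed = NULL,
                        default_sd = 8, bin_width = 1, support = c(18, 100),
                        pairing = c("paired", "cross")) {
  pairing <- match.arg(pairing)
  obs <- observed_count(trial)
  out <- data.frame(trial_id = trial$trial_id, group = trial$group,
                    expected_count = NA_real_, observed_count = obs,
                    ratio_mean = NA_real_, ratio_lo = NA_real_,
                    ratio_hi = NA_real_, n_samples = as.integer(n_samples),
                    seed = if (is.null(seed)) NA_integer_ else
                      as.integer(seed),
                    status = "ok", stringsAsFactors = FALSE)

  if (is.na(trial$mean_age) || is.na(trial$pct_women)) {
    out$status <- "excluded_missing_data"
    return(out)
  }
  params <- fit_truncated_normal(
    trial$mean_age,
    target_sd = if (is.na(trial$sd_age)) NULL else trial$sd_age,
    lower = if (is.na(trial$min_age)) -Inf else trial$min_age,
    upper = if (is.na(trial$max_age)) Inf else trial$max_age,
    default_sd = default_sd)
  dist <- age_sex_distribution(trial, params, bin_width, support)
  out$expected_count <- expected_count(trial, dist, model)

  if (obs == 0) {
    out$status <- "excluded_zero_events"
    return(out)
  }
  if (obs == 1) out$status <- "unstable_low_events"

  if (!is.null(seed)) set.seed(seed)
  coef_draws <- sample_coefficients(model, n_samples)
  py <- estimate_person_years(trial)
  e_draws <- expected_count_draws(py, dist, model$covariate_spec, coef_draws)
  o_draws <- rztpois(n_samples, obs)
  if (pairing == "paired") {
    ratios <- e_draws / o_draws
  } else {
    n_pairs <- min(as.double(n_samples)^2, 1e6)
    i <- sample.int(n_samples, n_pairs, replace = TRUE)
    j <- sample.int(n_samples, n_pairs, replace = TRUE)
    ratios <- e_draws[i] / o_draws[j]
  }
  q <- unname(stats::quantile(ratios, c(0.025, 0.975), type = 7))
  out$ratio_mean <- mean(ratios)
  out$ratio_lo <- q[1]
  out$ratio_hi <- q[2]
  out
}

#' Expected-to-observed ratios for a whole registry
#'
#' Applies [eo_ratio_mc()] to every trial, with per-trial sub-seeds derived
#' deterministically from `seed`. Trials lacking the age-sex information
#' needed for standardisation are retained in the output with status
#' `excluded_missing_data`.
#'
#' @param trials Data frame of trial records.
#' @param model A [rate_model()].
#' @param seed Integer seed.
#' @inheritParams eo_ratio_mc
#' @return Data frame with one E/O summary row per trial; the exclusion
#'   tally is attached as attribute `"exclusions"`.
#' @export
standardise_trials <- function(trials, model, n_samples = 10000, seed = 1L,
                               default_sd = 8, bin_width = 1,
                               support = c(18, 100),
                               pairing = c("paired", "cross")) {
  pairing <- match.arg(pairing)
  rows <- lapply(seq_len(nrow(trials)), function(i) {
    eo_ratio_mc(trials[i, , drop = FALSE], model, n_samples = n_samples,
                seed = stage_seed(seed + i, "eo"), default_sd = default_sd,
                bin_width = bin_width, support = support, pairing = pairing)
  })
  res <- do.call(rbind, rows)
  attr(res, "exclusions") <- table(res$status)
  res
}
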