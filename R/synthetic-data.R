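#' Generate a synthetic community cohort
#'
#' Simulates individual-level data emulating a primary-care cohort of new
#' users of antihypertensive drugs: ages from a normal distribution
#' truncated to the scenario's age range, sex by the scenario's mix,
#' follow-up censored at the administrative limit or an exponential
#' deregistration time (constant hazard derived from the annual dropout
#' probability), and event counts Poisson with rate
#' `exp(beta0 + beta_age*age + beta_sex*I(female))` per person-year,
#' multiplied by any condition-flag rate ratios. Event times are uniform
#' over each person's follow-up window (homogeneous Poisson process), which
#' is what the first-event/90-day sensitivity analysis needs. People flagged
#' with a recent myocardial infarction or stroke are excluded at
#' construction (they are unlikely to be treated for hypertension alone);
#' the number excluded is attached as attribute `n_excluded_mi_stroke`.
#'
#' Identical scenario and seed give byte-identical output.
#'
#' @param scenario A [cohort_scenario()].
#' @return Data frame with columns `person_id`, `age`, `sex`,
#'   `person_years`, `n_events`, `event_times` (list of event offsets in
#'   days), plus logical condition-flag columns `diabetes`, `heart_failure`,
#'   `ckd`.
#' @export
generate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  set.seed(scenario$seed)
  n <- scenario$n_persons
  age <- rtnorm(n, scenario$age_mean, scenario$age_sd,
                scenario$age_range[1], scenario$age_range[2])
  sex <- ifelse(stats::runif(n) < scenario$prop_female, "female", "male")
  prev <- scenario$condition_prevalence
  flags <- sapply(c("diabetes", "heart_failure", "ckd", "recent_mi_stroke"),
                  function(f) stats::runif(n) < prev[[f]])

  if (scenario$annual_dropout_prob > 0) {
    hazard <- -log(1 - scenario$annual_dropout_prob)
    t_drop <- stats::rexp(n, hazard)
  } else {
    t_drop <- rep(Inf, n)
  }
  py <- pmin(scenario$max_followup, t_drop)

  rr <- scenario$condition_rate_ratio
  log_rate <- scenario$beta0 + scenario$beta_age * age +
    scenario$beta_sex * (sex == "female") +
    log(rr[["diabetes"]]) * flags[, "diabetes"] +
    log(rr[["heart_failure"]]) * flags[, "heart_failure"] +
    log(rr[["ckd"]]) * flags[, "ckd"]
  rate <- exp(log_rate)              # beta0 = -Inf gives rate 0 exactly
  n_events <- stats::rpois(n, py * rate)
  event_times <- lapply(seq_len(n), function(i) {
    if (n_events[i] == 0L) numeric(0)
    else sort(stats::runif(n_events[i], 0, py[i] * DAYS_PER_YEAR))
  })

  cohort <- data.frame(person_id = sprintf("P%06d", seq_len(n)),
                       age = age, sex = sex, person_years = py,
                       n_events = n_events,
                       diabetes = flags[, "diabetes"],
                       heart_failure = flags[, "heart_failure"],
                       ckd = flags[, "ckd"],
                       stringsAsFactors = FALSE)
  cohort$event_times <- event_times
  keep <- !flags[, "recent_mi_stroke"]
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded_mi_stroke") <- sum(!keep)
  out
}

draw_category <- function(n, freqs) {
  freqs <- unlist(freqs)
  sample(names(freqs), n, replace = TRUE, prob = freqs / sum(freqs))
}

#' Generate a synthetic trial registry with known standardised ratios
#'
#' For each trial, draws a sample size, follow-up, reported mean age (older
#' trials above the group's minimum inclusion age, standard trials below),
#' sex mix and report-level covariates; computes the expected event count
#' `E` under `rate_model` through the same truncated-normal standardisation
#' machinery the estimation side uses (with person-time `follow-up x n`);
#' then draws the trial's total event count as
#' `Poisson(E / true_sr_group * exp(u))`, `u ~ Normal(0, random_intercept_sd^2)`.
#' For hard-outcome trials the total is split into clinical-endpoint events
#' and SAEs (so that their *pooled* count carries the ground truth); soft
#' trials report the total as SAEs. A fraction of trials has its reported
#' age summary masked to exercise downstream exclusion handling.
#'
#' The true per-group standardised ratio is therefore known by
#' construction, giving every downstream stage a parameter-recovery oracle.
#' Per-trial ground truth (expected count at generation, random intercept)
#' is attached as attribute `"truth"`.
#'
#' @param trial_scenario A [trial_scenario()].
#' @param rate_model A [rate_model()] providing the community rates.
#' @param default_sd Age SD (years) used in standardisation when a trial's
#'   SD is masked/unreported.
#' @return Data frame of trial records (one row per trial).
#' @export
generate_trials <- function(trial_scenario, rate_model, default_sd = 8) {
  stopifnot(inherits(trial_scenario, "trial_scenario"),
            inherits(rate_model, "rate_model"))
  ts <- trial_scenario
  set.seed(ts$seed)
  n_tr <- ts$n_trials_standard + ts$n_trials_older
  group <- rep(c("standard", "older"),
               c(ts$n_trials_standard, ts$n_trials_older))

  min_age <- ifelse(group == "older", ts$min_age_older, 18)
  max_age <- rep(NA_real_, n_tr)
  std <- group == "standard"
  has_cap <- std & stats::runif(n_tr) < 0.5
  max_age[has_cap] <- sample(c(70, 75, 80), sum(has_cap), replace = TRUE)

  mean_age <- numeric(n_tr)
  mean_age[std] <- rtnorm(sum(std), ts$mean_age_standard, 3,
                          pmax(30, min_age[std] + 5),
                          ifelse(is.na(max_age[std]), 70, max_age[std] - 5))
  mean_age[!std] <- rtnorm(sum(!std), ts$mean_age_older, 2,
                           ts$min_age_older + 3, 90)
  sd_age <- stats::runif(n_tr, 7, 10)
  # cap the reported SD below the feasibility limit of the trial's
  # truncation window (nearer-bound gap sets the attainable truncated SD)
  gap <- pmin(mean_age - min_age,
              ifelse(is.na(max_age), Inf, max_age - mean_age))
  sd_age <- pmin(sd_age, 0.8 * gap)
  sd_age[stats::runif(n_tr) >= ts$prop_sd_reported] <- NA_real_

  pw_mean <- ifelse(std, ts$pct_women_standard, ts$pct_women_older)
  conc <- 60
  pct_women <- stats::rbeta(n_tr, pw_mean * conc, (1 - pw_mean) * conc)

  n_participants <- if (ts$trial_size_range[1] == ts$trial_size_range[2]) {
    rep(ts$trial_size_range[1], n_tr)
  } else {
    sample(seq(ts$trial_size_range[1], ts$trial_size_range[2]), n_tr,
           replace = TRUE)
  }
  followup_days <- round(stats::runif(n_tr, ts$followup_range[1],
                                      ts$followup_range[2]), 1)

  mix <- ts$covariate_mix
  drug_class <- draw_category(n_tr, mix$drug_class)
  comparison_type <- draw_category(n_tr, mix$comparison_type)
  phase <- as.integer(draw_category(n_tr, mix$phase))
  outcome_type <- draw_category(n_tr, mix$outcome_type)

  trials <- data.frame(trial_id = sprintf("T%03d", seq_len(n_tr)),
                       group = group, min_age = min_age, max_age = max_age,
                       mean_age = mean_age, sd_age = sd_age,
                       pct_women = pct_women,
                       n_participants = n_participants,
                       followup_days = followup_days,
                       n_sae = 0L, n_endpoint_events = 0L,
                       outcome_type = outcome_type, drug_class = drug_class,
                       comparison_type = comparison_type, phase = phase,
                       arm = NA_character_, stringsAsFactors = FALSE)

  true_sr <- ifelse(std, ts$true_sr_standard, ts$true_sr_older)
  u <- stats::rnorm(n_tr, 0, ts$random_intercept_sd)
  e0 <- numeric(n_tr)
  for (i in seq_len(n_tr)) {
    tr <- trials[i, , drop = FALSE]
    if (tr$followup_days <= 0) { e0[i] <- 0; next }
    params <- fit_truncated_normal(
      tr$mean_age,
      target_sd = if (is.na(tr$sd_age)) NULL else tr$sd_age,
      lower = tr$min_age,
      upper = if (is.na(tr$max_age)) Inf else tr$max_age,
      default_sd = default_sd)
    dist <- age_sex_distribution(tr, params)
    e0[i] <- expected_count(tr, dist, rate_model)
    if (!is.finite(e0[i]) || e0[i] < 0) {
      stop("nonpositive/non-finite expected count generated for trial ",
           tr$trial_id, call. = FALSE)
    }
  }
  # Poisson mean consistent with the estimation-side person-time formula
  # follow-up x (n - 0.5 x SAEs): solving
  #   sr / exp(u) = followup x (n - 0.5 lambda) x rate / lambda
  # for lambda makes each trial's realised expected-to-observed estimand
  # exactly sr / exp(u), so log-scale heterogeneity is centred on log(sr)
  lambda <- ifelse(e0 > 0,
                   e0 / (true_sr / exp(u) + 0.5 * e0 / n_participants),
                   0)
  total <- stats::rpois(n_tr, lambda)
  # keep person-time positive: participants must outnumber half the SAEs
  total <- pmin(total, 2L * n_participants - 1L)
  hard <- outcome_type == "hard"
  n_endpoint <- integer(n_tr)
  n_endpoint[hard] <- stats::rbinom(sum(hard), total[hard], 0.3)
  trials$n_sae <- as.integer(total - n_endpoint)
  trials$n_endpoint_events <- as.integer(n_endpoint)

  if (ts$prop_missing_age > 0) {
    miss <- stats::runif(n_tr) < ts$prop_missing_age
    trials$mean_age[miss] <- NA_real_
    trials$sd_age[miss] <- NA_real_
  }

  fu_years <- days_to_years(followup_days)
  attr(trials, "truth") <- data.frame(
    trial_id = trials$trial_id, expected0 = e0,
    mu_rate = ifelse(e0 > 0, e0 / (fu_years * n_participants), 0),
    lambda = lambda, true_sr = true_sr, u = u)
  trials
}

#' Split placebo-controlled trials into arm-level records
#'
#' Builds arm-level synthetic records for every placebo-controlled trial in
#' a registry, with a known treatment-vs-control incidence rate ratio: each
#' trial's participants and expected count are split evenly between arms, a
#' shared trial-level random intercept is drawn, and arm SAE counts are
#' Poisson with the treatment arm's rate multiplied by `sqrt(true_arm_irr)`
#' and the control arm's divided by it (so their ratio is `true_arm_irr`
#' and the trial-level geometric mean is unchanged).
#'
#' @param trials Trial registry from [generate_trials()] (its `"truth"`
#'   attribute supplies the generation-time expected counts and SRs).
#' @param true_arm_irr True treatment-vs-control rate ratio.
#' @param random_intercept_sd SD of the shared trial-level log intercept.
#' @param seed Integer seed.
#' @return Data frame of arm-level trial records (two rows per
#'   placebo-controlled trial, `arm` set to `"treatment"`/`"control"`).
#' @export
generate_trial_arms <- function(trials, true_arm_irr = 0.8,
                                random_intercept_sd = 0.5, seed = 1L) {
  truth <- attr(trials, "truth")
  if (is.null(truth)) {
    stop("trials must carry the generator's 'truth' attribute ",
         "(use generate_trials output)", call. = FALSE)
  }
  keep <- trials$comparison_type == "placebo"
  if (!any(keep)) {
    stop("no placebo-controlled trials in the registry", call. = FALSE)
  }
  set.seed(seed)
  pieces <- lapply(which(keep), function(i) {
    tr <- trials[i, , drop = FALSE]
    tru <- truth[truth$trial_id == tr$trial_id, ]
    e_arm <- tru$expected0 / 2
    u <- stats::rnorm(1, 0, random_intercept_sd)
    lam <- e_arm / tru$true_sr * exp(u)
    n_arm <- floor(tr$n_participants / 2)
    arms <- rbind(tr, tr)
    arms$arm <- c("treatment", "control")
    arms$n_participants <- n_arm
    arms$n_sae <- c(stats::rpois(1, lam * sqrt(true_arm_irr)),
                    stats::rpois(1, lam / sqrt(true_arm_irr)))
    arms$n_sae <- pmin(arms$n_sae, 2L * n_arm - 1L)
    arms$n_endpoint_events <- 0L
    arms
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
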