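#' Community cohort scenario
#'
#' Describes the generative model for a synthetic community cohort of people
#' with hypertension starting antihypertensive treatment. Event counts follow
#' a log-linear Poisson rate model in age and sex, with person-time censored
#' by dropout. Defaults describe a cohort comparable to a national
#' primary-care sample of new users of renin-angiotensin-system drugs:
#' roughly 56,000 people, mean age about 61 (SD 14), half women, followed for
#' up to 3 years, with an overall event rate near 0.17 per person-year.
#'
#' The log rate for a person of a given age and sex is
#' `beta0 + beta_age * age + beta_sex * I(female)` plus `log` of any
#' condition-flag rate multipliers that apply. Condition flags (diabetes,
#' heart failure, chronic kidney disease) exist to support cohort-restriction
#' sensitivity analyses; their default rate multipliers are 1 so the base
#' coefficients retain their marginal meaning. People flagged with a recent
#' myocardial infarction or stroke are excluded during cohort construction,
#' mirroring how such patients are removed from an incident-user cohort
#' before analysis.
#'
#' @param n_persons Number of people to generate (before the MI/stroke
#'   construction exclusion).
#' @param age_mean,age_sd Mean and SD (years) of the underlying normal age
#'   distribution.
#' @param age_range Length-2 numeric; ages are truncated to this range.
#' @param prop_female Fraction of women.
#' @param beta0 Log baseline event rate (events per person-year) at age 0,
#'   male.
#' @param beta_age Log-rate change per year of age.
#' @param beta_sex Log-rate change for female vs male.
#' @param max_followup Administrative follow-up limit in years.
#' @param annual_dropout_prob Annual probability of deregistration; converted
#'   to a constant hazard.
#' @param condition_prevalence Named numeric: prevalence of each condition
#'   flag (`diabetes`, `heart_failure`, `ckd`, `recent_mi_stroke`).
#' @param condition_rate_ratio Named numeric: multiplicative rate effect of
#'   each flag (excluding `recent_mi_stroke`, which is an exclusion, not a
#'   covariate).
#' @param seed Integer seed controlling all randomness for this scenario.
#' @return An object of class `cohort_scenario`.
#' @export
cohort_scenario <- function(n_persons = 56036,
                            age_mean = 60.6,
                            age_sd = 13.9,
                            age_range = c(18, 100),
                            prop_female = 0.503,
                            beta0 = -3.85,
                            beta_age = 0.035,
                            beta_sex = -0.15,
                            max_followup = 3,
                            annual_dropout_prob = 0.05,
                            condition_prevalence = c(diabetes = 0.17,
                                                     heart_failure = 0.04,
                                                     ckd = 0.06,
                                                     recent_mi_stroke = 0.02),
                            condition_rate_ratio = c(diabetes = 1,
                                                     heart_failure = 1,
                                                     ckd = 1),
                            seed = 1L) {
  check_scalar_number(n_persons, "n_persons", lower = 1)
  check_scalar_number(age_mean, "age_mean")
  check_scalar_number(age_sd, "age_sd", lower = 1e-8)
  check_that(length(age_range) == 2 && all(is.finite(age_range)) &&
               age_range[1] < age_range[2],
             "age_range", "must be two finite numbers, lower < upper")
  check_scalar_number(prop_female, "prop_female", 0, 1)
  check_scalar_number(beta_age, "beta_age")
  check_scalar_number(beta_sex, "beta_sex")
  check_that(length(beta0) == 1 && (is.finite(beta0) || beta0 == -Inf),
             "beta0", "must be finite or -Inf (zero-rate limit)")
  check_scalar_number(max_followup, "max_followup", lower = 1e-8)
  check_scalar_number(annual_dropout_prob, "annual_dropout_prob", 0, 1)
  flags <- c("diabetes", "heart_failure", "ckd", "recent_mi_stroke")
  check_that(all(flags %in% names(condition_prevalence)),
             "condition_prevalence",
             paste("must name", paste(flags, collapse = ", ")))
  check_that(all(condition_prevalence >= 0 & condition_prevalence <= 1),
             "condition_prevalence", "entries must lie in [0, 1]")
  check_that(all(c("diabetes", "heart_failure", "ckd") %in%
                   names(condition_rate_ratio)),
             "condition_rate_ratio",
             "must name diabetes, heart_failure, ckd")
  check_that(all(condition_rate_ratio > 0), "condition_rate_ratio",
             "entries must be positive")
  check_scalar_number(seed, "seed")

  structure(list(n_persons = as.integer(n_persons), age_mean = age_mean,
                 age_sd = age_sd, age_range = age_range,
                 prop_female = prop_female, beta0 = beta0,
                 beta_age = beta_age, beta_sex = beta_sex,
                 max_followup = max_followup,
                 annual_dropout_prob = annual_dropout_prob,
                 condition_prevalence = condition_prevalence,
                 condition_rate_ratio = condition_rate_ratio,
                 seed = as.integer(seed)),
            class = "cohort_scenario")
}

#' Trial registry scenario
#'
#' Describes the generative model for a synthetic registry of hypertension
#' trials with a known standardised-ratio (SR) ground truth. Each trial's
#' SAE count is drawn as `Poisson(E / true_sr_group * exp(u))` where `E` is
#' the expected event count under a community rate model applied to the
#' trial's age-sex distribution and `u` is a trial-level normal random
#' intercept on the log scale. Trials in the `older` group carry a minimum
#' inclusion age of `min_age_older`; standard trials do not.
#'
#' Defaults reflect the registry the method was designed around: 99 standard
#' trials and 11 older-people trials, standard-trial mean ages near 55.6 and
#' older-trial mean ages near 73, 45% vs 55% women, sample sizes of a few
#' hundred to a couple of thousand, follow-up of a few weeks to a year, and
#' a true SR near 4.2 (standard) and 4.8 (older) with substantial trial-level
#' heterogeneity. `prop_missing_age` masks the age-sex fields of a fraction
#' of trials (default 20%, mirroring how often published reports omit them)
#' so that downstream exclusion handling is exercised.
#'
#' @param n_trials_standard,n_trials_older Number of trials per group.
#' @param true_sr_standard,true_sr_older True expected-to-observed ratio per
#'   group (> 1 means community event rates exceed trial SAE rates).
#' @param random_intercept_sd SD of the trial-level log-scale random
#'   intercept.
#' @param trial_size_range Length-2 integer: uniform range of per-trial
#'   sample sizes.
#' @param followup_range Length-2 numeric: uniform range of follow-up in
#'   days.
#' @param min_age_older Minimum inclusion age that defines an older-people
#'   trial (years).
#' @param mean_age_standard,mean_age_older Centres (years) of the reported
#'   mean-age distributions per group.
#' @param pct_women_standard,pct_women_older Expected fraction of women per
#'   group.
#' @param prop_missing_age Fraction of trials whose reported mean age (and
#'   sex mix) is masked as missing.
#' @param prop_sd_reported Fraction of trials that report an age SD.
#' @param covariate_mix Named list of category frequencies for `drug_class`,
#'   `comparison_type`, `phase` and `outcome_type`.
#' @param seed Integer seed.
#' @return An object of class `trial_scenario`.
#' @export
trial_scenario <- function(n_trials_standard = 99,
                           n_trials_older = 11,
                           true_sr_standard = 4.2,
                           true_sr_older = 4.8,
                           random_intercept_sd = 0.5,
                           trial_size_range = c(100, 2000),
                           followup_range = c(42, 365),
                           min_age_older = 60,
                           mean_age_standard = 55.6,
                           mean_age_older = 73.1,
                           pct_women_standard = 0.45,
                           pct_women_older = 0.55,
                           prop_missing_age = 0.2,
                           prop_sd_reported = 0.7,
                           covariate_mix = list(
                             drug_class = c(renin_inhibitor = 0.3,
                                            other = 0.7),
                             comparison_type = c(placebo = 0.2,
                                                 other_class_3char = 0.4,
                                                 other_class_5char = 0.4),
                             phase = c(`3` = 0.65, `4` = 0.35),
                             outcome_type = c(hard = 0.05, soft = 0.95)),
                           seed = 1L) {
  check_scalar_number(n_trials_standard, "n_trials_standard", lower = 1)
  check_scalar_number(n_trials_older, "n_trials_older", lower = 1)
  check_scalar_number(true_sr_standard, "true_sr_standard", lower = 1e-12)
  check_scalar_number(true_sr_older, "true_sr_older", lower = 1e-12)
  check_scalar_number(random_intercept_sd, "random_intercept_sd", lower = 0)
  check_that(length(trial_size_range) == 2 &&
               trial_size_range[1] >= 2 &&
               trial_size_range[1] <= trial_size_range[2],
             "trial_size_range", "must be two counts, 2 <= lower <= upper")
  check_that(length(followup_range) == 2 && followup_range[1] >= 0 &&
               followup_range[1] <= followup_range[2],
             "followup_range", "must be two day counts, 0 <= lower <= upper")
  check_scalar_number(min_age_older, "min_age_older", 18, 100)
  check_scalar_number(prop_missing_age, "prop_missing_age", 0, 1)
  check_scalar_number(prop_sd_reported, "prop_sd_reported", 0, 1)
  for (nm in c("drug_class", "comparison_type", "phase", "outcome_type")) {
    check_that(nm %in% names(covariate_mix), "covariate_mix",
               paste("must contain frequencies for", nm))
    check_that(all(covariate_mix[[nm]] >= 0) && sum(covariate_mix[[nm]]) > 0,
               "covariate_mix", paste(nm, "frequencies must be nonnegative"))
  }
  check_scalar_number(seed, "seed")

  structure(list(n_trials_standard = as.integer(n_trials_standard),
                 n_trials_older = as.integer(n_trials_older),
                 true_sr_standard = true_sr_standard,
                 true_sr_older = true_sr_older,
                 random_intercept_sd = random_intercept_sd,
                 trial_size_range = as.integer(round(trial_size_range)),
                 followup_range = followup_range,
                 min_age_older = min_age_older,
                 mean_age_standard = mean_age_standard,
                 mean_age_older = mean_age_older,
                 pct_women_standard = pct_women_standard,
                 pct_women_older = pct_women_older,
                 prop_missing_age = prop_missing_age,
                 prop_sd_reported = prop_sd_reported,
                 covariate_mix = covariate_mix,
                 seed = as.integer(seed)),
            class = "trial_scenario")
}
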