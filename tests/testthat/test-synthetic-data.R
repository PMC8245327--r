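test_that("scenario validation names the offending field", {
  expect_error(cohort_scenario(n_persons = 0), "n_persons")
  expect_error(cohort_scenario(prop_female = 1.4), "prop_female")
  expect_error(cohort_scenario(age_range = c(80, 20)), "age_range")
  expect_error(trial_scenario(true_sr_standard = -1), "true_sr_standard")
  expect_error(trial_scenario(random_intercept_sd = -0.1),
               "random_intercept_sd")
})

test_that("zero baseline rate forces zero event counts", {
  sc <- cohort_scenario(n_persons = 500, beta0 = -Inf, seed = 3)
  co <- generate_cohort(sc)
  expect_true(all(co$n_events == 0))
  expect_true(all(lengths(co$event_times) == 0))
})

test_that("cohort generation is deterministic under a fixed seed", {
  sc <- cohort_scenario(n_persons = 2000, seed = 11)
  expect_identical(generate_cohort(sc), generate_cohort(sc))
  ts <- trial_scenario(n_trials_standard = 20, n_trials_older = 5, seed = 12)
  expect_identical(generate_trials(ts, known_model),
                   generate_trials(ts, known_model))
})

test_that("cohort structure respects censoring and event-time invariants", {
  sc <- cohort_scenario(n_persons = 5000, seed = 21)
  co <- generate_cohort(sc)
  expect_true(all(co$person_years > 0 & co$person_years <= sc$max_followup))
  expect_identical(lengths(co$event_times), as.integer(co$n_events))
  limit <- co$person_years * 365.25
  ok <- vapply(seq_len(nrow(co)), function(i) {
    t <- co$event_times[[i]]
    length(t) == 0 || (all(t >= 0) && all(t <= limit[i]) && !is.unsorted(t))
  }, logical(1))
  expect_true(all(ok))
})

test_that("stratum event rates match the generative log-linear model", {
  sc <- cohort_scenario(n_persons = 120000, annual_dropout_prob = 0,
                        seed = 31)
  co <- generate_cohort(sc)
  # 10-year age bands by sex; only strata with >= 5000 people
  co$band <- cut(co$age, seq(20, 100, 10), right = FALSE)
  for (sx in c("male", "female")) {
    for (b in levels(co$band)) {
      idx <- co$sex == sx & !is.na(co$band) & co$band == b
      if (sum(idx) < 5000) next
      py <- sum(co$person_years[idx])
      obs_rate <- sum(co$n_events[idx]) / py
      # model rate averaged over the stratum's realised ages
      exp_rate <- mean(exp(sc$beta0 + sc$beta_age * co$age[idx] +
                             sc$beta_sex * (sx == "female")))
      mc_se <- sqrt(sum(co$n_events[idx])) / py
      expect_lt(abs(obs_rate - exp_rate), 3 * mc_se + 1e-12)
    }
  }
})

test_that("older trials carry the minimum inclusion age, standard do not", {
  ts <- trial_scenario(n_trials_standard = 40, n_trials_older = 10,
                       seed = 41)
  tr <- generate_trials(ts, known_model)
  expect_true(all(tr$min_age[tr$group == "older"] >= 60))
  expect_true(all(tr$min_age[tr$group == "standard"] < 60))
  expect_true(all(tr$mean_age > tr$min_age | is.na(tr$mean_age)))
})

test_that("null standardisation: true SR 1, no heterogeneity", {
  ts <- trial_scenario(n_trials_standard = 200, n_trials_older = 2,
                       true_sr_standard = 1, true_sr_older = 1,
                       random_intercept_sd = 0, prop_missing_age = 0,
                       seed = 51)
  tr <- generate_trials(ts, known_model)
  truth <- attr(tr, "truth")
  # estimand-side expected count: realised person-time x community rate
  pooled_e <- sum(estimate_person_years(tr) * truth$mu_rate)
  pooled_o <- sum(tr$n_sae + tr$n_endpoint_events)
  expect_lt(abs(pooled_o - pooled_e), 3 * sqrt(pooled_e))
})

test_that("pooled counts recover a planted SR of 4", {
  ts <- trial_scenario(n_trials_standard = 500, n_trials_older = 2,
                       true_sr_standard = 4, true_sr_older = 4,
                       random_intercept_sd = 0, prop_missing_age = 0,
                       seed = 61)
  tr <- generate_trials(ts, known_model)
  truth <- attr(tr, "truth")
  std <- tr$group == "standard"
  pooled_e <- sum((estimate_person_years(tr) * truth$mu_rate)[std])
  pooled_o <- sum(tr$n_sae[std] + tr$n_endpoint_events[std])
  expect_lt(abs(pooled_o - pooled_e / 4), 3 * sqrt(pooled_e / 4))
})

test_that("zero exposure yields zero SAE counts", {
  ts <- trial_scenario(n_trials_standard = 10, n_trials_older = 2,
                       trial_size_range = c(10, 10),
                       followup_range = c(0, 0), prop_missing_age = 0,
                       seed = 71)
  tr <- generate_trials(ts, known_model)
  expect_true(all(tr$n_sae == 0 & tr$n_endpoint_events == 0))
})

test_that("arm-level generation plants the treatment-vs-control ratio", {
  ts <- trial_scenario(n_trials_standard = 150, n_trials_older = 2,
                       random_intercept_sd = 0, prop_missing_age = 0,
                       covariate_mix = list(
                         drug_class = c(renin_inhibitor = 0.3, other = 0.7),
                         comparison_type = c(placebo = 1,
                                             other_class_3char = 0,
                                             other_class_5char = 0),
                         phase = c(`3` = 0.65, `4` = 0.35),
                         outcome_type = c(hard = 0, soft = 1)),
                       seed = 81)
  tr <- generate_trials(ts, known_model)
  arms <- generate_trial_arms(tr, true_arm_irr = 0.8,
                              random_intercept_sd = 0, seed = 82)
  expect_setequal(unique(arms$arm), c("treatment", "control"))
  o_t <- sum(arms$n_sae[arms$arm == "treatment"])
  o_c <- sum(arms$n_sae[arms$arm == "control"])
  # pooled ratio concentrates on the planted value
  se_log <- sqrt(1 / o_t + 1 / o_c)
  expect_lt(abs(log(o_t / o_c) - log(0.8)), 3 * se_log)
})
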