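test_that("person-years follow the attrition-adjusted formula", {
  expect_equal(estimate_person_years(
    make_trial(followup_days = 365.25, n_participants = 100, n_sae = 0)),
    100)
  expect_equal(estimate_person_years(
    make_trial(followup_days = 365.25, n_participants = 100, n_sae = 10)),
    95)
  expect_equal(estimate_person_years(
    make_trial(followup_days = 73.05, n_participants = 722, n_sae = 8)),
    0.2 * (722 - 4))
  expect_error(estimate_person_years(
    make_trial(n_participants = 5, n_sae = 10)), "exposure")
})

test_that("age-sex weights are a proper distribution matching the mean", {
  tr <- make_trial(mean_age = 55.6, sd_age = 8, min_age = 18, max_age = 70,
                   pct_women = 0.45)
  p <- fit_truncated_normal(55.6, 8, 18, 70)
  d <- age_sex_distribution(tr, p, bin_width = 1)
  expect_equal(sum(d$weight), 1, tolerance = 1e-9)
  expect_true(all(d$weight >= 0))
  expect_true(all(d$age >= 18 & d$age <= 70))
  expect_equal(sum(d$weight[d$sex == "female"]), 0.45, tolerance = 1e-9)
  # discretised mean within half a bin of the reported mean
  expect_lt(abs(sum(d$weight * d$age) - 55.6), 0.5)
})

test_that("an all-female trial puts no weight on male strata", {
  tr <- make_trial(pct_women = 1)
  p <- fit_truncated_normal(55, 8, 18, Inf)
  d <- age_sex_distribution(tr, p)
  expect_true(all(d$weight[d$sex == "male"] == 0))
})

test_that("missing sex mix is an exclusion signal", {
  tr <- make_trial(pct_women = NA)
  p <- fit_truncated_normal(55, 8, 18, Inf)
  expect_error(age_sex_distribution(tr, p), "ineligible")
})

test_that("expected counts are rate x exposure and linear in follow-up", {
  m0 <- rate_model(log(0.5), covariate_spec = "intercept")
  tr <- make_trial(followup_days = 365.25, n_participants = 100, n_sae = 10)
  p <- fit_truncated_normal(55, 8, 18, Inf)
  d <- age_sex_distribution(tr, p)
  expect_equal(expected_count(tr, d, m0), 0.5 * 95, tolerance = 1e-12)
  tr2 <- tr
  tr2$followup_days <- 2 * tr$followup_days
  expect_equal(expected_count(tr2, d, m0), 2 * expected_count(tr, d, m0),
               tolerance = 1e-12)
})

test_that("expected counts are stable under bin-width refinement", {
  tr <- make_trial(mean_age = 62, sd_age = 9, min_age = 18, max_age = 85)
  p <- fit_truncated_normal(62, 9, 18, 85)
  e1 <- expected_count(tr, age_sex_distribution(tr, p, bin_width = 1),
                       known_model)
  e05 <- expected_count(tr, age_sex_distribution(tr, p, bin_width = 0.5),
                        known_model)
  expect_lt(abs(e1 - e05) / e1, 0.001)
})

test_that("expected count agrees with an individual-level simulation", {
  tr <- make_trial(mean_age = 67, sd_age = 6, min_age = 60, max_age = NA,
                   pct_women = 0.55, n_participants = 800,
                   followup_days = 120, n_sae = 12)
  p <- fit_truncated_normal(67, 6, 60, Inf)
  d <- age_sex_distribution(tr, p)
  e <- expected_count(tr, d, known_model)
  set.seed(99)
  n_sim <- 200000
  ages <- pmin(rtnorm(n_sim, p$mu, p$sigma, 60, Inf), 100)
  sexes <- ifelse(stats::runif(n_sim) < tr$pct_women, "female", "male")
  sim_rate <- mean(predict_rate(known_model, ages, sexes))
  e_sim <- estimate_person_years(tr) * sim_rate
  expect_lt(abs(e - e_sim) / e_sim, 0.01)
})

test_that("degenerate-limit ratio concentrates on expected/observed", {
  tr <- make_trial(n_sae = 0)
  tr$n_sae <- 0L
  big_obs <- make_trial(n_sae = 1e6, n_participants = 4e6,
                        followup_days = 365.25)
  r <- eo_ratio_mc(big_obs, known_model, n_samples = 4000, seed = 2)
  expect_equal(r$status, "ok")
  expect_lt(abs(r$ratio_mean - r$expected_count / 1e6) /
              (r$expected_count / 1e6), 0.005)
  expect_lt(r$ratio_hi - r$ratio_lo, 0.02 * r$ratio_mean)
})

test_that("zero- and one-event trials get the contracted statuses", {
  r0 <- eo_ratio_mc(make_trial(n_sae = 0), known_model, n_samples = 100,
                    seed = 1)
  expect_equal(r0$status, "excluded_zero_events")
  expect_true(is.na(r0$ratio_mean))
  expect_gt(r0$expected_count, 0)
  r1 <- eo_ratio_mc(make_trial(n_sae = 1), known_model, n_samples = 100,
                    seed = 1)
  expect_equal(r1$status, "unstable_low_events")
  expect_false(is.na(r1$ratio_mean))
  rm <- eo_ratio_mc(make_trial(mean_age = NA), known_model,
                    n_samples = 100, seed = 1)
  expect_equal(rm$status, "excluded_missing_data")
})

test_that("hard-outcome trials pool endpoint events into the observed count", {
  tr <- make_trial(outcome_type = "hard", n_sae = 5, n_endpoint_events = 7)
  expect_equal(observed_count(tr), 12L)
  tr_soft <- make_trial(outcome_type = "soft", n_sae = 5,
                        n_endpoint_events = 7)
  expect_equal(observed_count(tr_soft), 5L)
  r <- eo_ratio_mc(tr, known_model, n_samples = 500, seed = 3)
  expect_equal(r$observed_count, 12L)
})

test_that("the MC ratio matches the zero-truncated reciprocal moment", {
  # with vcov = 0 the numerator is fixed, so
  # E[ratio] = expected * E[1/T], T ~ zero-truncated Poisson(observed);
  # oracle: direct series evaluation of the reciprocal moment
  obs <- 6
  k <- 1:200
  recip <- sum((1 / k) * stats::dpois(k, obs)) / (1 - exp(-obs))
  tr <- make_trial(n_sae = obs)
  r <- eo_ratio_mc(tr, known_model, n_samples = 20000, seed = 4)
  target <- r$expected_count * recip
  # MC standard error of the mean ratio
  set.seed(5)
  t_draws <- stats::rpois(20000, obs)
  t_draws <- t_draws[t_draws > 0]
  mc_se <- r$expected_count * stats::sd(1 / t_draws) / sqrt(20000)
  expect_lt(abs(r$ratio_mean - target), 3 * mc_se)
})

test_that("eo_ratio_mc is deterministic and pairing modes both work", {
  tr <- make_trial(n_sae = 8)
  a <- eo_ratio_mc(tr, fixture_model, n_samples = 2000, seed = 42)
  b <- eo_ratio_mc(tr, fixture_model, n_samples = 2000, seed = 42)
  expect_identical(a, b)
  cr <- eo_ratio_mc(tr, fixture_model, n_samples = 2000, seed = 42,
                    pairing = "cross")
  # cross-product pairing changes the draw pairing, not the location
  expect_lt(abs(cr$ratio_mean - a$ratio_mean) / a$ratio_mean, 0.1)
})

test_that("registry-level standardisation tallies exclusions", {
  ts <- trial_scenario(n_trials_standard = 15, n_trials_older = 3,
                       prop_missing_age = 0.3, seed = 404)
  tr <- generate_trials(ts, known_model)
  eo <- standardise_trials(tr, known_model, n_samples = 200, seed = 7)
  expect_equal(nrow(eo), nrow(tr))
  expect_equal(sum(is.na(tr$mean_age)),
               sum(eo$status == "excluded_missing_data"))
  expect_true(all(eo$status[observed_count(tr) == 0 &
                              !is.na(tr$mean_age)] ==
                    "excluded_zero_events"))
})
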