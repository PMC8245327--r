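# Small registries for model tests: flat_model gives every trial the same
# community rate, so group rate ratios equal ratios of true SRs.
make_registry <- function(n_std = 40, n_old = 10, sr_std = 2, sr_old = 2,
                          ri_sd = 0.3, seed = 1) {
  ts <- trial_scenario(n_trials_standard = n_std, n_trials_older = n_old,
                       true_sr_standard = sr_std, true_sr_older = sr_old,
                       random_intercept_sd = ri_sd, prop_missing_age = 0,
                       seed = seed)
  generate_trials(ts, flat_model)
}

test_that("flat-prior fixed effects agree with classical Poisson MLEs", {
  tr <- make_registry(n_std = 30, n_old = 8, seed = 11)
  py <- estimate_person_years(tr)
  ml <- stats::glm(tr$n_sae ~ I(tr$group == "older"),
                   family = stats::poisson(), offset = log(py))
  fit <- fit_sr_oracle <- fit_irr(tr, adjusted = FALSE,
                                  priors = hier_priors(flat = TRUE),
                                  sampler = quick_sampler(seed = 3,
                                                          iter = 3000,
                                                          chains = 2),
                                  random_intercept = FALSE)
  post <- fit$term_summaries
  b_irr <- post$median[post$term == "older" & post$scale == "log"]
  expect_lt(abs(b_irr - stats::coef(ml)[2]) / abs(stats::coef(ml)[2]), 0.02)
  b0 <- post$median[post$term == "intercept" & post$scale == "log"]
  expect_lt(abs(b0 - stats::coef(ml)[1]) / abs(stats::coef(ml)[1]), 0.02)
})

test_that("exponentiated summaries are the exp of log-scale summaries", {
  tr <- make_registry(seed = 21)
  fit <- suppressWarnings(fit_irr(tr, adjusted = FALSE,
                                  sampler = quick_sampler(seed = 5)))
  s <- fit$term_summaries
  for (term in unique(s$term)) {
    lg <- s[s$term == term & s$scale == "log", ]
    ex <- s[s$term == term & s$scale == "exp", ]
    expect_equal(ex$median, exp(lg$median), tolerance = 1e-12)
    expect_equal(ex$lo, exp(lg$lo), tolerance = 1e-12)
    expect_equal(ex$hi, exp(lg$hi), tolerance = 1e-12)
  }
})

test_that("identity standardisation gives group SR intervals covering 1", {
  tr <- make_registry(sr_std = 1, sr_old = 1, ri_sd = 0.02, seed = 31)
  eo <- standardise_trials(tr, flat_model, n_samples = 200, seed = 32)
  fit <- suppressWarnings(fit_sr(tr, eo, adjusted = FALSE,
                                 sampler = quick_sampler(seed = 33)))
  ct <- fit$contrasts
  for (nm in c("sr_standard", "sr_older")) {
    row <- ct[ct$name == nm, ]
    expect_lt(row$lo, 1)
    expect_gt(row$hi, 1)
  }
})

test_that("degenerate SR fit matches the closed-form standardised ratio", {
  tr <- make_registry(n_std = 30, n_old = 2, sr_std = 3, seed = 41)
  tr <- tr[tr$group == "standard", ]
  eo <- standardise_trials(tr, flat_model, n_samples = 100, seed = 42)
  fit <- suppressMessages(
    fit_sr(tr, eo, adjusted = FALSE, priors = hier_priors(flat = TRUE),
           sampler = quick_sampler(seed = 43, iter = 3000),
           random_intercept = FALSE))
  closed <- sum(eo$expected_count) / sum(observed_count(tr))
  expect_equal(fit$contrasts$name, "sr")
  expect_lt(abs(fit$contrasts$median - closed) / closed, 0.01)
})

test_that("trials without expected counts are excluded with reasons", {
  ts <- trial_scenario(n_trials_standard = 20, n_trials_older = 5,
                       prop_missing_age = 0.3, seed = 51)
  tr <- generate_trials(ts, flat_model)
  eo <- standardise_trials(tr, flat_model, n_samples = 100, seed = 52)
  fit <- suppressWarnings(fit_sr(tr, eo, adjusted = FALSE,
                                 sampler = quick_sampler(seed = 53)))
  n_missing <- sum(is.na(tr$mean_age))
  expect_equal(nrow(fit$excluded), n_missing)
  expect_true(all(grepl("age-sex", fit$excluded$reason)))
  expect_equal(fit$n_trials_used, nrow(tr) - n_missing)
})

test_that("a covariate level with no events triggers a separation warning", {
  tr <- make_registry(n_std = 20, n_old = 5, seed = 61)
  tr$outcome_type <- "soft"
  tr$outcome_type[1:3] <- "hard"
  tr$n_sae[1:3] <- 0L
  tr$n_endpoint_events[1:3] <- 0L
  w <- capture_warnings(
    fit_irr(tr, adjusted = TRUE, sampler = quick_sampler(seed = 62)))
  expect_true(any(grepl("hard_outcome", w)))
})

test_that("group contrast requires two trials per group", {
  tr <- make_registry(n_std = 10, n_old = 10, seed = 71)
  expect_error(fit_irr(tr[tr$group == "standard", ]), "each")
})

test_that("arm comparison recovers a planted null and flags single trials", {
  ts <- trial_scenario(n_trials_standard = 30, n_trials_older = 2,
                       random_intercept_sd = 0.2, prop_missing_age = 0,
                       covariate_mix = list(
                         drug_class = c(renin_inhibitor = 0.3, other = 0.7),
                         comparison_type = c(placebo = 1,
                                             other_class_3char = 0,
                                             other_class_5char = 0),
                         phase = c(`3` = 0.65, `4` = 0.35),
                         outcome_type = c(hard = 0, soft = 1)),
                       seed = 81)
  tr <- generate_trials(ts, flat_model)
  arms <- generate_trial_arms(tr, true_arm_irr = 1,
                              random_intercept_sd = 0.2, seed = 82)
  fit <- suppressWarnings(compare_arms(arms,
                                       sampler = quick_sampler(seed = 83)))
  ct <- fit$contrasts[fit$contrasts$name == "irr_treatment_vs_control", ]
  expect_lt(ct$lo, 1)
  expect_gt(ct$hi, 1)
  one <- arms[arms$trial_id == arms$trial_id[1], ]
  expect_warning(compare_arms(one, sampler = quick_sampler(seed = 84)),
                 "single trial")
  none <- arms[0, ]
  expect_message(expect_null(compare_arms(none)), "no placebo")
})

test_that("posterior summaries are reproducible and stable across seeds", {
  tr <- make_registry(n_std = 25, n_old = 6, seed = 91)
  f1 <- suppressWarnings(fit_irr(tr, adjusted = FALSE,
                                 sampler = quick_sampler(seed = 7)))
  f2 <- suppressWarnings(fit_irr(tr, adjusted = FALSE,
                                 sampler = quick_sampler(seed = 7)))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(fit_irr(tr, adjusted = FALSE,
                                 sampler = quick_sampler(seed = 8)))
  # different seed: medians agree within Monte Carlo error
  m1 <- f1$contrasts$median
  m3 <- f3$contrasts$median
  mc_se <- stats::sd(f1$contrast_draws[[1]]) /
    sqrt(min(f1$diagnostics$ess, na.rm = TRUE))
  expect_lt(abs(m1 - m3), 6 * mc_se)
})
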