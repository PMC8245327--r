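test_that("leave-one-out produces one variant per trial and finds outliers", {
  # 10 identical standard trials plus one planted extreme outlier
  tr <- do.call(rbind, lapply(1:10, function(i) {
    make_trial(trial_id = sprintf("S%02d", i), n_sae = 20,
               n_participants = 500, followup_days = 180)
  }))
  tr2 <- rbind(tr, make_trial(trial_id = "OUT", n_sae = 400,
                              n_participants = 500, followup_days = 180))
  eo <- standardise_trials(tr2, known_model, n_samples = 50, seed = 1)
  fit_fn <- function(t) suppressWarnings(
    fit_sr(t, eo, adjusted = FALSE, sampler = quick_sampler(seed = 1,
                                                            iter = 800)))
  rep <- suppressMessages(leave_one_out(tr2, fit_fn, contrast = "sr"))
  expect_s3_class(rep, "sensitivity_report")
  expect_equal(nrow(rep$variants), nrow(tr2))
  delta <- abs(rep$variants$estimate - rep$baseline$estimate)
  expect_equal(rep$variants$excluded_trial[which.max(delta)], "OUT")
  # exchangeable trials give near-identical variant estimates
  ident <- rep$variants$estimate[rep$variants$excluded_trial
                                 %in% tr$trial_id]
  expect_lt(diff(range(ident)) / stats::median(ident), 0.25)
})

test_that("leave-one-out matches the count contract at 11 trials", {
  tr <- do.call(rbind, lapply(1:11, function(i) {
    make_trial(trial_id = sprintf("T%02d", i),
               group = if (i <= 8) "standard" else "older",
               min_age = if (i <= 8) 18 else 60,
               mean_age = if (i <= 8) 55 else 72,
               n_sae = 15 + i)
  }))
  fit_fn <- function(t) suppressWarnings(
    fit_irr(t, adjusted = FALSE, sampler = quick_sampler(seed = 2,
                                                         iter = 600)))
  rep <- leave_one_out(tr, fit_fn)
  expect_equal(nrow(rep$variants), 11L)
})

test_that("failing variants are flagged without aborting the analysis", {
  tr <- do.call(rbind, lapply(1:6, function(i) {
    make_trial(trial_id = sprintf("T%02d", i),
               group = if (i <= 4) "standard" else "older",
               min_age = if (i <= 4) 18 else 60,
               mean_age = if (i <= 4) 55 else 72, n_sae = 12)
  }))
  # dropping either older trial leaves <2 older trials: those variants fail
  fit_fn <- function(t) suppressWarnings(
    fit_irr(t, adjusted = FALSE, sampler = quick_sampler(seed = 3,
                                                         iter = 600)))
  rep <- leave_one_out(tr, fit_fn)
  expect_equal(sum(rep$variants$flagged), 2L)
  expect_true(all(is.na(rep$variants$estimate[rep$variants$flagged])))
  expect_true(all(!is.na(rep$variants$estimate[!rep$variants$flagged])))
})

test_that("cohort restriction filters by flags and validates columns", {
  co <- fixture_cohort[1:1000, ]
  co$diabetes <- FALSE
  co$heart_failure <- FALSE
  co$ckd <- FALSE
  expect_equal(nrow(suppressMessages(restrict_cohort(co))), 1000)
  co$diabetes[1:10] <- TRUE
  out <- suppressMessages(restrict_cohort(co))
  expect_equal(nrow(out), 990)
  expect_equal(attr(out, "n_excluded"), 10L)
  co$ckd <- NULL
  expect_error(restrict_cohort(co), "ckd")
  all_flagged <- fixture_cohort[1:50, ]
  all_flagged$diabetes <- TRUE
  empty <- suppressMessages(restrict_cohort(all_flagged))
  expect_equal(nrow(empty), 0)
  expect_error(fit_rate_model(empty), "nonempty|positive")
})

test_that("restricting a cohort with planted high-risk flags lowers rates", {
  sc <- cohort_scenario(n_persons = 40000,
                        condition_prevalence = c(diabetes = 0.3,
                                                 heart_failure = 0,
                                                 ckd = 0,
                                                 recent_mi_stroke = 0),
                        condition_rate_ratio = c(diabetes = 2,
                                                 heart_failure = 1,
                                                 ckd = 1),
                        seed = 7)
  co <- generate_cohort(sc)
  m_full <- fit_rate_model(co)
  m_restr <- fit_rate_model(suppressMessages(restrict_cohort(co)))
  ages <- seq(30, 90, 10)
  for (sx in c("male", "female")) {
    expect_true(all(predict_rate(m_restr, ages, sx) <
                      predict_rate(m_full, ages, sx)))
  }
})

test_that("follow-up truncation censors at window, first event, or end", {
  co <- data.frame(person_id = c("a", "b", "c"),
                   age = 60, sex = "male",
                   person_years = c(3, 3, 0.1),
                   n_events = c(0L, 2L, 0L),
                   stringsAsFactors = FALSE)
  co$event_times <- list(numeric(0), c(10, 200), numeric(0))
  out <- truncate_followup_first_event(co, window_days = 90)
  expect_equal(out$person_years, c(90 / 365.25, 10 / 365.25, 0.1))
  expect_equal(out$n_events, c(0L, 1L, 0L))
  expect_equal(lengths(out$event_times), c(0L, 1L, 0L))
  co2 <- co
  co2$event_times <- NULL
  expect_error(truncate_followup_first_event(co2), "event_times")
})

test_that("window beyond follow-up leaves event-free persons unchanged", {
  co <- fixture_cohort[fixture_cohort$n_events == 0, ][1:500, ]
  out <- truncate_followup_first_event(co, window_days = 10000)
  expect_equal(out$person_years, co$person_years)
  expect_equal(out$n_events, rep(0L, nrow(co)))
})

test_that("90-day first-event rates agree with the constant-hazard model", {
  # under a homogeneous event process, censoring at the first event is an
  # exact exposure-truncation: the intercept is unchanged in expectation
  sc <- cohort_scenario(n_persons = 60000, beta_age = 0, beta_sex = 0,
                        beta0 = log(0.4), seed = 17)
  co <- generate_cohort(sc)
  m_full <- fit_rate_model(co, covariate_spec = "intercept")
  m_trunc <- fit_rate_model(truncate_followup_first_event(co, 90),
                            covariate_spec = "intercept")
  se <- sqrt(m_trunc$vcov[1, 1] + m_full$vcov[1, 1])
  expect_lt(abs(m_trunc$coefficients - m_full$coefficients), 3 * se)
})
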