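#!/usr/bin/env Rscript

# Stage 1: simulate the study inputs.
#
# Generates (a) a community cohort of people with hypertension starting
# RAAS-class antihypertensives, with age-sex log-linear event rates, and
# (b) a 110-trial registry (99 standard, 11 older-people) whose SAE counts
# embed a known standardised ratio per group, so every later stage can be
# checked against ground truth.

library(trialsae)

SEED <- 1L
out_dir <- "results/analysis"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

sc <- cohort_scenario(seed = stage_seed(SEED, "cohort"))
cohort <- generate_cohort(sc)
cat(sprintf("cohort: %d persons (%d excluded for recent MI/stroke), %d events over %.0f person-years\n",
            nrow(cohort), attr(cohort, "n_excluded_mi_stroke"),
            sum(cohort$n_events), sum(cohort$person_years)))
write_cohort(cohort, file.path(out_dir, "cohort.csv"))

# the registry generator needs the community rates; use the true
# generative coefficients here (the fitted model comes in stage 2)
true_model <- rate_model(c(sc$beta0, sc$beta_age, sc$beta_sex),
                         covariate_spec = c("intercept", "age", "sex"))
ts <- trial_scenario(seed = stage_seed(SEED, "trials"))
trials <- generate_trials(ts, true_model)
cat(sprintf("registry: %d trials (%d older-people, %d with masked age summaries)\n",
            nrow(trials), sum(trials$group == "older"),
            sum(is.na(trials$mean_age))))
cat(sprintf("true standardised ratios: standard %.2f, older %.2f; trial-level log-SD %.2f\n",
            ts$true_sr_standard, ts$true_sr_older, ts$random_intercept_sd))
write_trials(trials, file.path(out_dir, "trials.csv"))

arms <- generate_trial_arms(trials, true_arm_irr = 0.8,
                            random_intercept_sd = 0.5,
                            seed = stage_seed(SEED, "arms"))
cat(sprintf("arm-level records: %d placebo-controlled trials split into arms (true arm IRR 0.8)\n",
            length(unique(arms$trial_id))))
write_trials(arms, file.path(out_dir, "trial_arms.csv"))
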