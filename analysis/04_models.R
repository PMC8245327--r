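#!/usr/bin/env Rscript

# Stage 4: hierarchical Poisson models.
#
# (a) IRR: SAE rates in older-people vs standard trials, person-time
#     offset, random trial intercepts; unadjusted and adjusted for trial
#     characteristics (the adjusted model is the primary analysis).
# (b) SR: observed counts with the log community-expected count as offset;
#     reported on the expected/observed scale, per group, with the ratio
#     of SRs (older vs standard).
# (c) Arm comparison: treatment vs placebo arms within placebo-controlled
#     trials (SAEs are expected to be similar across arms).

library(trialsae)

SEED <- 1L
out_dir <- "results/analysis"
trials <- read_trials(file.path(out_dir, "trials.csv"))
arms <- read_trials(file.path(out_dir, "trial_arms.csv"))
model <- read_rate_model(file.path(out_dir, "rate_model.json"))
eo <- read.csv(file.path(out_dir, "eo_ratios.csv"))

fits <- list(
  irr_unadjusted = fit_irr(trials, adjusted = FALSE,
                           sampler = hier_sampler(seed = stage_seed(SEED,
                                                                    "irr"))),
  irr_adjusted = fit_irr(trials, adjusted = TRUE,
                         sampler = hier_sampler(seed = stage_seed(SEED,
                                                                  "irr"))),
  sr_unadjusted = fit_sr(trials, eo, adjusted = FALSE,
                         sampler = hier_sampler(seed = stage_seed(SEED,
                                                                  "sr"))),
  sr_adjusted = fit_sr(trials, eo, adjusted = TRUE,
                       sampler = hier_sampler(seed = stage_seed(SEED,
                                                                "sr"))),
  arms = compare_arms(arms,
                      sampler = hier_sampler(seed = stage_seed(SEED,
                                                               "arms"))))

for (nm in names(fits)) print(fits[[nm]])

py <- estimate_person_years(trials)
rate <- trials$n_sae / py
cat(sprintf("median SAE rate per person-year: standard %.3f, older %.3f\n",
            median(rate[trials$group == "standard"]),
            median(rate[trials$group == "older"])))

tidy <- do.call(rbind, lapply(names(fits), function(nm) {
  tidy_hier_fit(fits[[nm]], model = nm)
}))
write.csv(tidy, file.path(out_dir, "model_results.csv"), row.names = FALSE)
cat("tidy posterior summaries written to",
    file.path(out_dir, "model_results.csv"), "\n")
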