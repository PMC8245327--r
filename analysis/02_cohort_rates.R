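#!/usr/bin/env Rscript

# Stage 2: fit the community age-sex event-rate model.
#
# Poisson log-linear regression of each person's hospitalisation/death
# count on age and sex with log person-years offset. Only the coefficients
# and their variance-covariance matrix travel downstream (the export
# contract of a secure data environment); they are serialised as JSON.

library(trialsae)

out_dir <- "results/analysis"
cohort <- read_cohort(file.path(out_dir, "cohort.csv"))

model <- fit_rate_model(cohort)
print(model)

# rate per person-year doubles roughly every 20 years of age here
cat(sprintf("rate at age 60: male %.3f, female %.3f per person-year\n",
            predict_rate(model, 60, "male"),
            predict_rate(model, 60, "female")))

# specification check: a quadratic age term should add little
quad <- fit_rate_model(cohort,
                       covariate_spec = c("intercept", "age", "age2", "sex"))
cat(sprintf("quadratic age term: %.2e (SE %.2e) -- linear age retained\n",
            quad$coefficients["age2"], sqrt(quad$vcov["age2", "age2"])))

write_rate_model(model, file.path(out_dir, "rate_model.json"))
cat("rate model exported to", file.path(out_dir, "rate_model.json"), "\n")
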