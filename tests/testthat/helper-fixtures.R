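# Shared fixtures, built once per test run.

# A moderate synthetic cohort and its fitted rate model: large enough that
# the coefficients are well determined, small enough to fit in seconds.
fixture_cohort <- generate_cohort(
  cohort_scenario(n_persons = 20000, seed = 101))
fixture_model <- fit_rate_model(fixture_cohort)

# A rate model with exactly known coefficients and zero vcov, for oracle
# checks that need the community rates to be a fixed, known quantity.
known_model <- rate_model(c(-3.85, 0.035, -0.15),
                          vcov = matrix(0, 3, 3),
                          covariate_spec = c("intercept", "age", "sex"))

# An age/sex-free (intercept-only) rate model: every trial has the same
# expected rate, so group rate ratios equal the ratio of true SRs.
flat_model <- rate_model(log(0.15), vcov = matrix(0, 1, 1),
                         covariate_spec = "intercept")

# One-row trial record with sensible defaults, overridable per test.
make_trial <- function(trial_id = "T001", group = "standard",
                       min_age = 18, max_age = NA, mean_age = 55,
                       sd_age = 8, pct_women = 0.45,
                       n_participants = 500, followup_days = 180,
                       n_sae = 10, n_endpoint_events = 0L,
                       outcome_type = "soft", drug_class = "other",
                       comparison_type = "placebo", phase = 3L,
                       arm = NA_character_) {
  data.frame(trial_id = trial_id, group = group, min_age = min_age,
             max_age = max_age, mean_age = mean_age, sd_age = sd_age,
             pct_women = pct_women, n_participants = n_participants,
             followup_days = followup_days, n_sae = as.integer(n_sae),
             n_endpoint_events = as.integer(n_endpoint_events),
             outcome_type = outcome_type, drug_class = drug_class,
             comparison_type = comparison_type, phase = as.integer(phase),
             arm = arm, stringsAsFactors = FALSE)
}

# Reduced sampler for tests that only need point contrasts.
quick_sampler <- function(seed = 1L, iter = 1200, chains = 2) {
  hier_sampler(chains = chains, iter = iter, seed = seed)
}

# Quadrature oracle for truncated-normal moments: numerical integration of
# the truncated density, independent of the closed forms in the package.
quad_tnorm_moments <- function(mu, sigma, lower, upper) {
  lo <- if (is.finite(lower)) lower else mu - 15 * sigma
  hi <- if (is.finite(upper)) upper else mu + 15 * sigma
  mass <- stats::integrate(function(x) stats::dnorm(x, mu, sigma),
                           lo, hi, rel.tol = 1e-12)$value
  m1 <- stats::integrate(function(x) x * stats::dnorm(x, mu, sigma),
                         lo, hi, rel.tol = 1e-12)$value / mass
  m2 <- stats::integrate(function(x) (x - m1)^2 * stats::dnorm(x, mu, sigma),
                         lo, hi, rel.tol = 1e-12)$value / mass
  list(mean = m1, sd = sqrt(m2))
}
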