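#' Default end-to-end run configuration
#'
#' One list holding every tunable of the pipeline: the synthetic scenario
#' overrides (empty means the scenario constructors' defaults), the rate
#' model's covariate terms, standardisation settings, model priors and
#' sampler settings, and the sensitivity-analysis toggles. The
#' leave-one-out refits use a reduced sampler (they only need point
#' contrasts, not full diagnostics).
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    paths = list(trials_csv = NULL, cohort_csv = NULL,
                 rate_model_json = NULL),
    write_cohort = FALSE,
    cohort = list(),
    trials = list(),
    covariate_spec = c("intercept", "age", "sex"),
    standardise = list(n_samples = 10000, default_sd = 8, bin_width = 1,
                       pairing = "paired"),
    models = list(beta_sd = 2.5, sd_u_scale = 1,
                  chains = 4, iter = 2000,
                  arms = TRUE, true_arm_irr = 0.8,
                  arm_random_intercept_sd = 0.5),
    sensitivity = list(leave_one_out = TRUE, cohort_restriction = TRUE,
                       followup_90d = TRUE, window_days = 90,
                       loo_chains = 2, loo_iter = 800)
  )
}

write_results_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation (or load), community rate-model
#' fit, trial-registry simulation (or load), per-trial expected-to-observed
#' standardisation, the hierarchical IRR and SR models (unadjusted and
#' adjusted) plus the treatment-vs-placebo arm comparison, and the three
#' sensitivity analyses. Every stage derives its randomness from the single
#' configured seed via [stage_seed()], logs its inputs and exclusions, and
#' writes its results table under `out_dir`; a JSON manifest recording the
#' configuration, seed, package version and output checksums is written
#' last, and re-running from that manifest reproduces every results file
#' byte for byte.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress stage progress messages.
#' @return Invisibly, a list with the in-memory cohort, rate model, trials,
#'   E/O table, model fits, sensitivity reports and manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  seed <- config$seed
  files <- character(0)
  t_start <- Sys.time()

  # --- cohort ---
  if (!is.null(config$paths$cohort_csv)) {
    say("loading cohort from ", config$paths$cohort_csv)
    cohort <- read_cohort(config$paths$cohort_csv)
  } else {
    cohort_over <- config$cohort[setdiff(names(config$cohort), "seed")]
    sc <- do.call(cohort_scenario,
                  c(cohort_over, list(seed = stage_seed(seed, "cohort"))))
    cohort <- generate_cohort(sc)
    say("simulated cohort: ", nrow(cohort), " persons (",
        attr(cohort, "n_excluded_mi_stroke"),
        " excluded at construction for recent MI/stroke), ",
        sum(cohort$n_events), " events")
  }
  if (isTRUE(config$write_cohort)) {
    files <- c(files, write_cohort(cohort, file.path(out_dir, "cohort.csv")))
  }

  # --- community rate model ---
  if (!is.null(config$paths$rate_model_json)) {
    model <- read_rate_model(config$paths$rate_model_json)
  } else {
    model <- fit_rate_model(cohort, covariate_spec = config$covariate_spec)
  }
  files <- c(files, write_rate_model(model,
                                     file.path(out_dir, "rate_model.json")))
  say("rate model: ", paste(sprintf("%s=%.4f", model$covariate_spec,
                                    model$coefficients), collapse = ", "))

  # --- trial registry ---
  if (!is.null(config$paths$trials_csv)) {
    say("loading trials from ", config$paths$trials_csv)
    trials <- read_trials(config$paths$trials_csv)
  } else {
    trial_over <- config$trials[setdiff(names(config$trials), "seed")]
    ts <- do.call(trial_scenario,
                  c(trial_over, list(seed = stage_seed(seed, "trials"))))
    trials <- generate_trials(ts, model,
                              default_sd = config$standardise$default_sd)
    say("simulated registry: ", nrow(trials), " trials (",
        sum(trials$group == "older"), " older-people)")
  }
  files <- c(files, write_trials(trials, file.path(out_dir, "trials.csv")))

  # --- standardisation ---
  eo <- standardise_trials(trials, model,
                           n_samples = config$standardise$n_samples,
                           seed = stage_seed(seed, "eo"),
                           default_sd = config$standardise$default_sd,
                           bin_width = config$standardise$bin_width,
                           pairing = config$standardise$pairing)
  excl <- attr(eo, "exclusions")
  say("E/O ratios: ", paste(names(excl), as.integer(excl), sep = "=",
                            collapse = ", "))
  files <- c(files, write_results_csv(eo, file.path(out_dir,
                                                    "eo_ratios.csv")))

  # --- hierarchical models ---
  mc <- config$models
  priors <- hier_priors(beta_sd = mc$beta_sd, sd_u_scale = mc$sd_u_scale)
  sampler_for <- function(stage) {
    hier_sampler(chains = mc$chains, iter = mc$iter,
                 seed = stage_seed(seed, stage))
  }
  fits <- list()
  both_groups <- all(table(trials$group)[c("standard", "older")] >= 2,
                     na.rm = TRUE) &&
    length(unique(trials$group)) == 2
  if (both_groups) {
    say("fitting IRR models")
    fits$irr_unadjusted <- fit_irr(trials, adjusted = FALSE, priors = priors,
                                   sampler = sampler_for("irr"))
    fits$irr_adjusted <- fit_irr(trials, adjusted = TRUE, priors = priors,
                                 sampler = sampler_for("irr"))
  } else {
    say("only one trial group present: IRR group contrast not estimable")
  }
  say("fitting SR models")
  fits$sr_unadjusted <- fit_sr(trials, eo, adjusted = FALSE, priors = priors,
                               sampler = sampler_for("sr"))
  fits$sr_adjusted <- fit_sr(trials, eo, adjusted = TRUE, priors = priors,
                             sampler = sampler_for("sr"))

  arm_trials <- NULL
  if (isTRUE(mc$arms) && !is.null(attr(trials, "truth")) &&
      any(trials$comparison_type == "placebo")) {
    arm_trials <- generate_trial_arms(
      trials, true_arm_irr = mc$true_arm_irr,
      random_intercept_sd = mc$arm_random_intercept_sd,
      seed = stage_seed(seed, "arms"))
    files <- c(files, write_trials(arm_trials,
                                   file.path(out_dir, "trial_arms.csv")))
    say("fitting arm comparison on ",
        length(unique(arm_trials$trial_id)), " placebo-controlled trials")
    fits$arms <- compare_arms(arm_trials, priors = priors,
                              sampler = sampler_for("arms"))
  }

  tidy <- do.call(rbind, lapply(names(fits), function(nm) {
    tidy_hier_fit(fits[[nm]], model = nm)
  }))
  files <- c(files, write_results_csv(tidy,
                                      file.path(out_dir,
                                                "model_results.csv")))

  # --- headline summary ---
  py <- estimate_person_years(trials)
  sae_rate <- trials$n_sae / py
  summary_tab <- data.frame(
    quantity = c("median_sae_rate_standard", "median_sae_rate_older",
                 "n_trials", "n_trials_older"),
    value = c(stats::median(sae_rate[trials$group == "standard"]),
              stats::median(sae_rate[trials$group == "older"]),
              nrow(trials), sum(trials$group == "older")))
  files <- c(files, write_results_csv(summary_tab,
                                      file.path(out_dir, "summary.csv")))

  # --- sensitivity analyses ---
  sens <- list()
  sn <- config$sensitivity
  loo_sampler <- hier_sampler(chains = sn$loo_chains, iter = sn$loo_iter,
                              seed = stage_seed(seed, "sensitivity"))
  if (isTRUE(sn$leave_one_out) && both_groups) {
    say("sensitivity: leave-one-out refits (", 2 * nrow(trials), " fits)")
    loo_irr <- leave_one_out(
      trials,
      function(tr) fit_irr(tr, adjusted = TRUE, priors = priors,
                           sampler = loo_sampler),
      baseline = fits$irr_adjusted)
    loo_sr <- leave_one_out(
      trials,
      function(tr) fit_sr(tr, eo, adjusted = TRUE, priors = priors,
                          sampler = loo_sampler),
      contrast = "ratio_of_srs", baseline = fits$sr_adjusted)
    sens$leave_one_out <- list(irr = loo_irr, sr = loo_sr)
    loo_tab <- rbind(data.frame(model = "irr_adjusted", loo_irr$variants),
                     data.frame(model = "sr_adjusted", loo_sr$variants))
    files <- c(files, write_results_csv(loo_tab,
                                        file.path(out_dir,
                                                  "sensitivity_loo.csv")))
  }
  refit_sr_on_cohort <- function(cohort_variant, label, stage) {
    m2 <- fit_rate_model(cohort_variant,
                         covariate_spec = config$covariate_spec)
    eo2 <- standardise_trials(trials, m2,
                              n_samples = config$standardise$n_samples,
                              seed = stage_seed(seed, "eo"),
                              default_sd = config$standardise$default_sd,
                              bin_width = config$standardise$bin_width,
                              pairing = config$standardise$pairing)
    fit2 <- fit_sr(trials, eo2, adjusted = TRUE, priors = priors,
                   sampler = hier_sampler(chains = mc$chains,
                                          iter = mc$iter,
                                          seed = stage_seed(seed, stage)))
    list(rate_model = m2, eo = eo2, fit = fit2,
         tidy = tidy_hier_fit(fit2, model = label))
  }
  if (isTRUE(sn$cohort_restriction)) {
    say("sensitivity: cohort restriction (diabetes/heart failure/CKD)")
    restricted <- restrict_cohort(cohort)
    sens$cohort_restriction <-
      refit_sr_on_cohort(restricted, "sr_adjusted_restricted_cohort", "sr")
    files <- c(files,
               write_results_csv(sens$cohort_restriction$tidy,
                                 file.path(out_dir,
                                           "sensitivity_restricted.csv")))
  }
  if (isTRUE(sn$followup_90d)) {
    say("sensitivity: ", sn$window_days, "-day first-event follow-up")
    truncated <- truncate_followup_first_event(cohort, sn$window_days)
    sens$followup_90d <-
      refit_sr_on_cohort(truncated, "sr_adjusted_90d_first_event", "sr")
    files <- c(files,
               write_results_csv(sens$followup_90d$tidy,
                                 file.path(out_dir,
                                           "sensitivity_90d.csv")))
  }

  # --- manifest ---
  manifest <- list(
    package = "trialsae",
    version = as.character(utils::packageVersion("trialsae")),
    created = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    elapsed_seconds = as.numeric(difftime(Sys.time(), t_start,
                                          units = "secs")),
    seed = seed,
    config = config,
    exclusions = as.list(excl),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  say(sprintf("pipeline complete in %.1f s; outputs in %s",
              manifest$elapsed_seconds, out_dir))
  invisible(list(cohort = cohort, rate_model = model, trials = trials,
                 arm_trials = arm_trials, eo = eo, fits = fits,
                 summary = summary_tab, sensitivity = sens,
                 manifest = manifest))
}

#' Re-run a pipeline from an emitted manifest
#'
#' Reads the configuration embedded in a run manifest and executes
#' [run_pipeline()] with it; given the same package version, the emitted
#' result files are byte-identical to the original run's.
#'
#' @param manifest_path Path to a `manifest.json` from a previous run.
#' @param out_dir Output directory for the re-run.
#' @param quiet Suppress progress messages.
#' @return As [run_pipeline()].
#' @export
rerun_from_manifest <- function(manifest_path, out_dir, quiet = FALSE) {
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  config <- merge_config(default_config(), manifest$config)
  run_pipeline(config, out_dir, quiet = quiet)
}
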