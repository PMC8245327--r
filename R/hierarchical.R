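#' Prior settings for the hierarchical Poisson models
#'
#' Weakly informative defaults: Normal(0, `beta_sd`) on fixed effects
#' (all covariates here are indicators) and half-Normal(0, `sd_u_scale`) on
#' the trial-level random-intercept SD. `flat = TRUE` replaces the
#' fixed-effect priors with effectively flat Normal(0, 1000) priors, which
#' is what the classical-MLE agreement oracle uses.
#'
#' @param beta_sd Prior SD for fixed effects (log scale).
#' @param sd_u_scale Scale of the half-normal prior on the random-intercept
#'   SD.
#' @param flat Use effectively flat fixed-effect priors.
#' @return List of prior settings.
#' @export
hier_priors <- function(beta_sd = 2.5, sd_u_scale = 1, flat = FALSE) {
  list(beta_sd = beta_sd, sd_u_scale = sd_u_scale, flat = flat)
}

#' Sampler settings for the hierarchical Poisson models
#'
#' Defaults: 4 chains of 2000 iterations each, the first half used for
#' adaptation and burn-in, convergence judged by the potential
#' scale-reduction statistic against `rhat_threshold`.
#'
#' @param chains Number of MCMC chains.
#' @param iter Total iterations per chain (warm-up included).
#' @param warmup Iterations discarded per chain (adaptation + burn-in).
#' @param seed Integer seed; chain c uses `seed + c`.
#' @param rhat_threshold Flag nonconvergence above this value.
#' @return List of sampler settings.
#' @export
hier_sampler <- function(chains = 4, iter = 2000, warmup = floor(iter / 2),
                         seed = 1L, rhat_threshold = 1.01) {
  stopifnot(chains >= 1, iter > warmup, warmup >= 2)
  list(chains = as.integer(chains), iter = as.integer(iter),
       warmup = as.integer(warmup), seed = as.integer(seed),
       rhat_threshold = rhat_threshold)
}

# Core engine: random-intercept (or plain) Poisson regression with a log
# offset, fitted by Gibbs/Metropolis sampling through rjags. Returns the
# pooled fixed-effect (+ sd_u) draws, per-chain draws for diagnostics, and
# summary statistics.
fit_hier_poisson <- function(y, log_offset, X, group = NULL,
                             priors = hier_priors(),
                             sampler = hier_sampler()) {
  stopifnot(length(y) == length(log_offset), nrow(X) == length(y),
            all(is.finite(log_offset)))
  # block samplers for GLMMs: much better mixing for Poisson models with
  # per-trial random intercepts than the default slice samplers
  rjags::load.module("glm", quiet = TRUE)
  K <- ncol(X)
  beta_prec <- if (isTRUE(priors$flat)) 1e-6 else priors$beta_sd^-2
  dat <- list(y = as.integer(y), off = as.numeric(log_offset),
              X = as.matrix(X), N = length(y), K = K,
              beta_prec = beta_prec)
  monitor <- "beta"
  if (!is.null(group)) {
    g <- as.integer(factor(group))
    dat$g <- g
    dat$J <- max(g)
    dat$sd_u_prec <- priors$sd_u_scale^-2
    model_str <- "model {
      for (i in 1:N) {
        y[i] ~ dpois(mu[i])
        log(mu[i]) <- off[i] + inprod(X[i, 1:K], beta[1:K]) + u[g[i]]
      }
      for (j in 1:J) { u[j] ~ dnorm(0, tau_u) }
      sd_u ~ dnorm(0, sd_u_prec) T(0,)
      tau_u <- pow(sd_u, -2)
      for (k in 1:K) { beta[k] ~ dnorm(0, beta_prec) }
    }"
    monitor <- c(monitor, "sd_u")
  } else {
    model_str <- "model {
      for (i in 1:N) {
        y[i] ~ dpois(mu[i])
        log(mu[i]) <- off[i] + inprod(X[i, 1:K], beta[1:K])
      }
      for (k in 1:K) { beta[k] ~ dnorm(0, beta_prec) }
    }"
  }
  inits <- lapply(seq_len(sampler$chains), function(c) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = sampler$seed + c)
  })
  n_adapt <- max(100L, floor(sampler$warmup / 2))
  n_burn <- sampler$warmup - n_adapt
  jm <- rjags::jags.model(textConnection(model_str), data = dat,
                          inits = inits, n.chains = sampler$chains,
                          n.adapt = n_adapt, quiet = TRUE)
  if (n_burn > 0) update(jm, n_burn, progress.bar = "none")
  samp <- rjags::coda.samples(jm, monitor,
                              n.iter = sampler$iter - sampler$warmup,
                              progress.bar = "none")
  # name beta columns after the design matrix
  new_names <- colnames(samp[[1]])
  for (k in seq_len(K)) {
    new_names[new_names == sprintf("beta[%d]", k)] <- colnames(X)[k]
  }
  new_names[new_names == "beta"] <- colnames(X)[1]
  samp <- lapply(samp, function(m) { colnames(m) <- new_names; m })
  samp <- coda::as.mcmc.list(lapply(samp, coda::as.mcmc))
  samp
}

draw_summary <- function(x) {
  q <- unname(stats::quantile(x, c(0.025, 0.5, 0.975), type = 7))
  c(mean = mean(x), median = q[2], lo = q[1], hi = q[3])
}

# Rhat and effective sample size per parameter; NA when undefined
# (single chain or zero-variance draws).
chain_diagnostics <- function(samp) {
  pars <- colnames(samp[[1]])
  rhat <- rep(NA_real_, length(pars))
  if (length(samp) >= 2) {
    gd <- tryCatch(coda::gelman.diag(samp, multivariate = FALSE,
                                     autoburnin = FALSE)$psrf[, 1],
                   error = function(e) rep(NA_real_, length(pars)))
    rhat <- as.numeric(gd)
  }
  ess <- tryCatch(as.numeric(coda::effectiveSize(samp)),
                  error = function(e) rep(NA_real_, length(pars)))
  data.frame(term = pars, rhat = rhat, ess = ess,
             stringsAsFactors = FALSE)
}

warn_separation <- function(y, X) {
  for (k in seq_len(ncol(X))) {
    nm <- colnames(X)[k]
    if (nm == "intercept") next
    v <- X[, k]
    if (!all(v %in% c(0, 1))) next
    for (lev in unique(v)) {
      idx <- v == lev
      if (any(idx) && sum(y[idx]) == 0) {
        warning("all observed counts are zero at level ", nm, " = ", lev,
                ": the corresponding contrast is only weakly identified",
                call. = FALSE)
      }
    }
  }
}

trial_design <- function(trials, adjusted, include_group = TRUE) {
  X <- matrix(1, nrow(trials), 1, dimnames = list(NULL, "intercept"))
  if (include_group) {
    X <- cbind(X, older = as.numeric(trials$group == "older"))
  }
  if (adjusted) {
    X <- cbind(X,
               renin_inhibitor =
                 as.numeric(trials$drug_class == "renin_inhibitor"),
               comp_3char =
                 as.numeric(trials$comparison_type == "other_class_3char"),
               comp_5char =
                 as.numeric(trials$comparison_type == "other_class_5char"),
               phase4 = as.numeric(trials$phase == 4),
               hard_outcome = as.numeric(trials$outcome_type == "hard"))
  }
  X
}

new_hier_fit <- function(samp, contrast_draws, n_trials_used, excluded,
                         sampler, model_label) {
  pooled <- as.matrix(do.call(rbind, lapply(samp, unclass)))
  diag_tab <- chain_diagnostics(samp)
  summ <- do.call(rbind, lapply(colnames(pooled), function(p) {
    s_log <- draw_summary(pooled[, p])
    # centiles transform monotonely; only the mean needs the exp draws
    s_exp <- c(mean = mean(exp(pooled[, p])), exp(s_log[c("median", "lo",
                                                          "hi")]))
    rbind(data.frame(term = p, scale = "log", t(s_log)),
          data.frame(term = p, scale = "exp", t(s_exp)))
  }))
  summ <- merge(summ, diag_tab, by = "term", sort = FALSE)
  contrasts <- NULL
  if (length(contrast_draws)) {
    contrasts <- do.call(rbind, lapply(names(contrast_draws), function(nm) {
      data.frame(name = nm, t(draw_summary(contrast_draws[[nm]])))
    }))
  }
  max_rhat <- suppressWarnings(max(diag_tab$rhat, na.rm = TRUE))
  converged <- !is.finite(max_rhat) || max_rhat <= sampler$rhat_threshold
  if (!converged) {
    warning(model_label, ": convergence diagnostic above threshold (max ",
            "Rhat = ", format(max_rhat, digits = 4), "); treat posterior ",
            "summaries with caution", call. = FALSE)
  }
  structure(list(model = model_label, draws = pooled,
                 contrast_draws = contrast_draws,
                 term_summaries = summ, contrasts = contrasts,
                 diagnostics = diag_tab, converged = converged,
                 n_trials_used = n_trials_used, excluded = excluded,
                 sampler = sampler),
            class = "hier_fit")
}

#' @export
print.hier_fit <- function(x, ...) {
  cat("Hierarchical Poisson fit:", x$model, "\n")
  cat(sprintf("%d trials used; converged: %s\n", x$n_trials_used,
              x$converged))
  if (!is.null(x$contrasts)) {
    cat("Derived quantities (posterior median [95% CrI]):\n")
    for (i in seq_len(nrow(x$contrasts))) {
      cat(sprintf("  %-28s %6.3f [%.3f, %.3f]\n", x$contrasts$name[i],
                  x$contrasts$median[i], x$contrasts$lo[i],
                  x$contrasts$hi[i]))
    }
  }
  invisible(x)
}

#' Incidence rate ratio between older-people and standard trials
#'
#' Fits a hierarchical Poisson regression of each trial's SAE count on
#' older-trial status with a random intercept per trial and the log of
#' estimated person-time as offset; `adjusted = TRUE` adds the trial-report
#' covariates (renin-inhibitor drug, comparison type, phase, outcome type;
#' reference levels: non-renin-inhibitor, placebo comparison, phase 3, soft
#' outcome). The derived contrast `irr_older_vs_standard` is the
#' exponentiated older-vs-standard log-rate difference with its 95%
#' credible interval (2.5th/97.5th posterior centiles).
#'
#' @param trials Data frame of trial records.
#' @param adjusted Include the trial-characteristic covariate set.
#' @param priors A [hier_priors()].
#' @param sampler A [hier_sampler()].
#' @param random_intercept Set `FALSE` to drop the trial random intercept
#'   (degenerate-variance oracle).
#' @return A `hier_fit` object.
#' @export
fit_irr <- function(trials, adjusted = TRUE, priors = hier_priors(),
                    sampler = hier_sampler(), random_intercept = TRUE) {
  groups <- table(factor(trials$group, levels = c("standard", "older")))
  if (any(groups < 2)) {
    stop("need at least 2 trials in each of the standard and older groups ",
         "for the group contrast", call. = FALSE)
  }
  y <- trials$n_sae
  py <- estimate_person_years(trials)
  X <- trial_design(trials, adjusted)
  warn_separation(y, X)
  samp <- fit_hier_poisson(y, log(py), X,
                           group = if (random_intercept) trials$trial_id,
                           priors = priors, sampler = sampler)
  pooled <- do.call(rbind, lapply(samp, unclass))
  contrasts <- list(irr_older_vs_standard = exp(pooled[, "older"]))
  new_hier_fit(samp, contrasts, nrow(trials),
               excluded = data.frame(trial_id = character(0),
                                     reason = character(0)),
               sampler,
               model_label = paste0("IRR (", if (adjusted) "adjusted"
                                    else "unadjusted", ")"))
}

#' Standardised ratio of community-expected to trial-observed events
#'
#' Fits the hierarchical Poisson regression of observed trial event counts
#' (SAEs, pooled with endpoint events for hard-outcome trials) with the log
#' of the community-expected count as offset. The likelihood estimates
#' observed/expected; all reported quantities are inverted to the
#' expected-to-observed scale, so SR > 1 means community hospitalisation and
#' death rates exceed trial SAE rates. With both groups present, the
#' derived quantities are `sr_standard`, `sr_older` and their ratio
#' `ratio_of_srs` (older vs standard); with one group, a single `sr`.
#' Trials without a computable expected count are excluded with a recorded
#' reason.
#'
#' @param trials Data frame of trial records.
#' @param eo E/O summary table from [standardise_trials()] (supplies
#'   expected counts and exclusion statuses).
#' @inheritParams fit_irr
#' @return A `hier_fit` object.
#' @export
fit_sr <- function(trials, eo, adjusted = TRUE, priors = hier_priors(),
                   sampler = hier_sampler(), random_intercept = TRUE) {
  m <- match(trials$trial_id, eo$trial_id)
  stopifnot(!anyNA(m))
  expct <- eo$expected_count[m]
  usable <- is.finite(expct) & expct > 0
  excluded <- data.frame(trial_id = trials$trial_id[!usable],
                         reason = ifelse(
                           eo$status[m][!usable] == "excluded_missing_data",
                           "insufficient age-sex data for expected count",
                           "nonpositive expected count"),
                         stringsAsFactors = FALSE)
  trials <- trials[usable, , drop = FALSE]
  expct <- expct[usable]
  y <- observed_count(trials)
  both_groups <- length(unique(trials$group)) == 2
  X <- trial_design(trials, adjusted, include_group = both_groups)
  warn_separation(y, X)
  samp <- fit_hier_poisson(y, log(expct), X,
                           group = if (random_intercept) trials$trial_id,
                           priors = priors, sampler = sampler)
  pooled <- do.call(rbind, lapply(samp, unclass))
  # invert observed/expected to the expected/observed (SR) scale
  if (both_groups) {
    contrasts <- list(
      sr_standard = exp(-pooled[, "intercept"]),
      sr_older = exp(-(pooled[, "intercept"] + pooled[, "older"])),
      ratio_of_srs = exp(-pooled[, "older"]))
  } else {
    contrasts <- list(sr = exp(-pooled[, "intercept"]))
    message("only one trial group present: per-group SR reported, group ",
            "contrast not estimable")
  }
  new_hier_fit(samp, contrasts, nrow(trials), excluded, sampler,
               model_label = paste0("SR (", if (adjusted) "adjusted"
                                    else "unadjusted", ")"))
}

#' Treatment vs placebo arm comparison of SAE rates
#'
#' Fits a hierarchical Poisson model on arm-level records of
#' placebo-controlled trials, with the trial as the random-intercept
#' grouping and log arm person-time as offset. The derived contrast is the
#' treatment-vs-control incidence rate ratio.
#'
#' @param arm_trials Arm-level trial records (`arm` column set).
#' @inheritParams fit_irr
#' @return A `hier_fit` object, or `NULL` (with a message) when no
#'   placebo-controlled arm-level records are available.
#' @export
compare_arms <- function(arm_trials, priors = hier_priors(),
                         sampler = hier_sampler()) {
  rows <- !is.na(arm_trials$arm) & arm_trials$comparison_type == "placebo"
  arm_trials <- arm_trials[rows, , drop = FALSE]
  if (nrow(arm_trials) == 0) {
    message("no placebo-controlled arm-level records: arm comparison ",
            "not performed")
    return(NULL)
  }
  n_trials <- length(unique(arm_trials$trial_id))
  if (n_trials < 2) {
    warning("arm comparison based on a single trial: estimates will be ",
            "low-information with a wide credible interval", call. = FALSE)
  }
  y <- arm_trials$n_sae
  py <- estimate_person_years(arm_trials)
  X <- cbind(intercept = rep(1, nrow(arm_trials)),
             treatment = as.numeric(arm_trials$arm == "treatment"))
  samp <- fit_hier_poisson(y, log(py), X, group = arm_trials$trial_id,
                           priors = priors, sampler = sampler)
  pooled <- do.call(rbind, lapply(samp, unclass))
  contrasts <- list(irr_treatment_vs_control = exp(pooled[, "treatment"]))
  new_hier_fit(samp, contrasts, n_trials,
               excluded = data.frame(trial_id = character(0),
                                     reason = character(0)),
               sampler, model_label = "arm IRR (treatment vs placebo)")
}

#' Tidy one-row-per-quantity results table for a hierarchical fit
#'
#' @param fit A `hier_fit`.
#' @param model Optional label overriding the fit's own.
#' @return Data frame with columns `model`, `kind`, `term`, `scale`,
#'   `mean`, `median`, `lo`, `hi`, `rhat`, `ess`.
#' @export
tidy_hier_fit <- function(fit, model = fit$model) {
  if (is.null(fit)) return(NULL)
  terms <- data.frame(model = model, kind = "term",
                      fit$term_summaries, stringsAsFactors = FALSE)
  out <- terms
  if (!is.null(fit$contrasts)) {
    ct <- data.frame(model = model, kind = "derived",
                     term = fit$contrasts$name, scale = "exp",
                     mean = fit$contrasts$mean, median = fit$contrasts$median,
                     lo = fit$contrasts$lo, hi = fit$contrasts$hi,
                     rhat = NA_real_, ess = NA_real_,
                     stringsAsFactors = FALSE)
    out <- rbind(terms[, names(ct)], ct)
  }
  out
}
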