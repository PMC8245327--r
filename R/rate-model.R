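#' Construct a community rate model directly from coefficients
#'
#' A `rate_model` holds the fitted (or specified) coefficients of a
#' log-linear Poisson model for the rate of emergency hospitalisation or
#' death per person-year, together with the variance-covariance matrix of
#' the coefficient estimates. This is exactly the object a secure data
#' environment would export: the individual-level cohort never leaves, only
#' the coefficients and their vcov.
#'
#' @param coefficients Named numeric vector on the log-rate (per person-year)
#'   scale, in the order of `covariate_spec` terms.
#' @param vcov Variance-covariance matrix of the coefficients (may be a zero
#'   matrix for a model treated as known).
#' @param covariate_spec Character vector of terms; supported terms are
#'   `"intercept"`, `"age"` (linear, years), `"age2"` (age squared) and
#'   `"sex"` (indicator of female).
#' @param n_fitted,total_events,total_person_years Fit metadata (optional).
#' @return An object of class `rate_model`.
#' @export
rate_model <- function(coefficients, vcov = NULL,
                       covariate_spec = c("intercept", "age", "sex"),
                       n_fitted = NA_integer_, total_events = NA_integer_,
                       total_person_years = NA_real_) {
  p <- length(covariate_spec)
  check_that(length(coefficients) == p, "coefficients",
             "length must match covariate_spec")
  check_that(all(covariate_spec %in% c("intercept", "age", "age2", "sex")),
             "covariate_spec",
             "terms must be among intercept, age, age2, sex")
  if (is.null(vcov)) vcov <- matrix(0, p, p)
  vcov <- as.matrix(vcov)
  check_that(all(dim(vcov) == c(p, p)), "vcov",
             "dimensions must match the coefficient count")
  check_that(max(abs(vcov - t(vcov))) <= 1e-10, "vcov",
             "must be symmetric (within 1e-10)")
  coefficients <- as.numeric(coefficients)
  names(coefficients) <- covariate_spec
  dimnames(vcov) <- list(covariate_spec, covariate_spec)
  structure(list(covariate_spec = covariate_spec,
                 coefficients = coefficients, vcov = vcov,
                 n_fitted = n_fitted, total_events = total_events,
                 total_person_years = total_person_years),
            class = "rate_model")
}

# Design matrix for a rate model's covariate terms.
# age in years; sex is "male"/"female" (indicator of female).
rate_design <- function(covariate_spec, age, sex) {
  n <- max(length(age), length(sex))
  age <- rep_len(age, n)
  female <- as.numeric(rep_len(sex, n) == "female")
  cols <- lapply(covariate_spec, function(term) {
    switch(term,
           intercept = rep(1, n),
           age = age,
           age2 = age^2,
           sex = female,
           stop("unknown covariate term: ", term, call. = FALSE))
  })
  X <- do.call(cbind, cols)
  colnames(X) <- covariate_spec
  X
}

#' Fit the community age-sex event-rate model
#'
#' Maximum-likelihood Poisson log-linear regression of each person's event
#' count on age and sex, with log person-years as the exposure offset.
#' Internally ages are centred at 60 years to stabilise the intercept; the
#' exported coefficients are translated back to the natural (uncentred) age
#' scale, so `predict_rate()` and downstream standardisation can use raw
#' ages. People with zero person-time cannot contribute exposure and are
#' dropped with a warning reporting the count.
#'
#' @param cohort Data frame of cohort persons with columns `age`, `sex`
#'   (`"male"`/`"female"`), `person_years`, `n_events`.
#' @param covariate_spec Character vector of model terms (see
#'   [rate_model()]); default linear age + sex indicator. Supported
#'   alternatives include quadratic age (`c("intercept","age","age2","sex")`).
#' @param epsilon,maxit IRLS convergence tolerance on the deviance change
#'   and iteration cap.
#' @return A [rate_model()].
#' @export
fit_rate_model <- function(cohort,
                           covariate_spec = c("intercept", "age", "sex"),
                           epsilon = 1e-8, maxit = 100) {
  check_that(nrow(cohort) > 0, "cohort", "must be nonempty")
  needed <- c("age", "sex", "person_years", "n_events")
  check_that(all(needed %in% names(cohort)), "cohort",
             paste("must contain columns", paste(needed, collapse = ", ")))
  check_that(all(is.finite(cohort$age)), "age", "must be finite")
  check_that("intercept" %in% covariate_spec, "covariate_spec",
             "must include an intercept")
  zero_pt <- cohort$person_years <= 0
  if (any(zero_pt)) {
    warning(sum(zero_pt), " person(s) with zero person-time dropped from ",
            "the rate-model fit", call. = FALSE)
    cohort <- cohort[!zero_pt, , drop = FALSE]
  }
  check_that(nrow(cohort) > 0 && sum(cohort$person_years) > 0,
             "cohort", "total person-years must be positive")
  if (sum(cohort$n_events) == 0) {
    stop("all event counts are zero: the log rate is unbounded below; ",
         "supply a cohort with events or impose a rate floor", call. = FALSE)
  }

  centre <- 60
  X <- rate_design(covariate_spec, cohort$age - centre, cohort$sex)
  fit <- stats::glm.fit(X, cohort$n_events,
                        family = stats::poisson(),
                        offset = log(cohort$person_years),
                        control = stats::glm.control(epsilon = epsilon,
                                                     maxit = maxit))
  if (!fit$converged) {
    stop("Poisson rate-model fit did not converge", call. = FALSE)
  }
  beta <- fit$coefficients
  # vcov from the final IRLS weights: (X' W X)^{-1}
  W <- fit$weights
  XtWX <- crossprod(X * sqrt(W))
  V <- solve(XtWX)

  # translate age centring back to the natural scale:
  # with centred age a' = a - c the linear predictor
  # b0 + b1 a' + b2 a'^2 + ... equals
  # (b0 - b1 c + b2 c^2) + (b1 - 2 b2 c) a + b2 a^2
  A <- diag(length(beta))
  dimnames(A) <- list(covariate_spec, covariate_spec)
  if ("age" %in% covariate_spec) {
    A["intercept", "age"] <- -centre
  }
  if ("age2" %in% covariate_spec) {
    A["intercept", "age2"] <- centre^2
    A["age", "age2"] <- -2 * centre
  }
  beta_nat <- drop(A %*% beta)
  V_nat <- A %*% V %*% t(A)

  rate_model(beta_nat, V_nat, covariate_spec,
             n_fitted = nrow(cohort),
             total_events = sum(cohort$n_events),
             total_person_years = sum(cohort$person_years))
}

#' Predict the event rate for an age and sex
#'
#' Evaluates `exp(linear predictor)` of a fitted [rate_model()]; the result
#' is an event rate per person-year and is strictly positive. Ages outside
#' the plausible adult range trigger a warning (extrapolation), not an
#' error.
#'
#' @param model A [rate_model()].
#' @param age Ages in years (vectorised).
#' @param sex `"male"` or `"female"` (vectorised).
#' @param age_bounds Warn when extrapolating outside this range.
#' @return Event rate(s) per person-year.
#' @export
predict_rate <- function(model, age, sex, age_bounds = c(18, 100)) {
  stopifnot(inherits(model, "rate_model"))
  if (any(age < age_bounds[1] | age > age_bounds[2])) {
    warning("predicting outside the configured age range [",
            age_bounds[1], ", ", age_bounds[2], "]: extrapolation",
            call. = FALSE)
  }
  X <- rate_design(model$covariate_spec, age, sex)
  drop(exp(X %*% model$coefficients))
}

#' Sample coefficient vectors from the model's sampling distribution
#'
#' Draws from a multivariate normal with mean the point estimates and
#' covariance the fitted variance-covariance matrix — the uncertainty
#' propagation step for expected counts. A Cholesky factor is used when the
#' vcov is positive definite, an eigen square root otherwise (covering the
#' degenerate vcov = 0 case, where every draw equals the point estimates).
#'
#' @param model A [rate_model()].
#' @param n_samples Number of draws (>= 1).
#' @param seed Integer seed; fixed seed gives an identical draw matrix.
#' @param repair Clip slightly negative eigenvalues to zero instead of
#'   erroring (default FALSE).
#' @return Matrix with `n_samples` rows, one column per coefficient.
#' @export
sample_coefficients <- function(model, n_samples, seed = NULL,
                                repair = FALSE) {
  stopifnot(inherits(model, "rate_model"))
  check_scalar_number(n_samples, "n_samples", lower = 1)
  p <- length(model$coefficients)
  V <- model$vcov
  ev <- eigen(V, symmetric = TRUE)
  tol <- -1e-8 * max(abs(ev$values), 1e-300)
  if (min(ev$values) < tol) {
    if (!repair) {
      stop("vcov is not positive semi-definite (min eigenvalue ",
           format(min(ev$values)), "); rerun with repair = TRUE to clip ",
           "negative eigenvalues to zero", call. = FALSE)
    }
  }
  lam <- pmax(ev$values, 0)
  L <- ev$vectors %*% (sqrt(lam) * t(ev$vectors))
  if (!is.null(seed)) set.seed(seed)
  Z <- matrix(stats::rnorm(n_samples * p), nrow = n_samples)
  draws <- Z %*% L
  draws <- sweep(draws, 2, model$coefficients, `+`)
  colnames(draws) <- model$covariate_spec
  draws
}

#' Write / read a rate model as plain text (JSON)
#'
#' The serialisation mirrors the export contract of a secure data platform:
#' ordered term names, the coefficient vector, the row-major vcov and fit
#' metadata, as human-readable JSON.
#'
#' @param model A [rate_model()].
#' @param path File path.
#' @return `write_rate_model` returns `path` invisibly; `read_rate_model`
#'   returns a [rate_model()].
#' @export
write_rate_model <- function(model, path) {
  stopifnot(inherits(model, "rate_model"))
  obj <- list(covariate_spec = model$covariate_spec,
              coefficients = unname(model$coefficients),
              vcov = as.vector(t(model$vcov)),
              n_fitted = model$n_fitted,
              total_events = model$total_events,
              total_person_years = model$total_person_years)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_rate_model
#' @export
read_rate_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(obj$covariate_spec)
  V <- matrix(obj$vcov, nrow = p, byrow = TRUE)
  rate_model(obj$coefficients, V, obj$covariate_spec,
             n_fitted = obj$n_fitted, total_events = obj$total_events,
             total_person_years = obj$total_person_years)
}

#' @export
print.rate_model <- function(x, ...) {
  cat("Community event-rate model (Poisson, log person-year offset)\n")
  se <- sqrt(diag(x$vcov))
  tab <- data.frame(term = x$covariate_spec,
                    estimate = unname(x$coefficients),
                    se = unname(se))
  print(tab, row.names = FALSE, digits = 5)
  if (!is.na(x$n_fitted)) {
    cat(sprintf("n = %d persons, %d events over %.0f person-years\n",
                x$n_fitted, x$total_events, x$total_person_years))
  }
  invisible(x)
}
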