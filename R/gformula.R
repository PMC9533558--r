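# The parametric g-formula estimator: survey-weighted pooled logistic
# discrete-time hazard models with metal-by-diet interactions,
# counterfactual standardization under intervention rules, risk ratio /
# risk difference contrasts, and nonparametric bootstrap percentile CIs.
#
# All covariates are measured at baseline, so counterfactual risks are
# computed in closed form (product over intervals of model-predicted
# hazards) -- no Monte-Carlo simulation step is needed in the estimator.

#' Specify a pooled logistic hazard model
#'
#' The discrete-time hazard of the selected cause is modelled on the logit
#' scale as a polynomial in the interval index plus baseline covariates,
#' log2 metal exposures (mutually adjusted), one diet exposure, and
#' metal-by-diet interaction terms.
#'
#' @param cause outcome cause selector: `"all"`, `"cvd"`, `"cancer"`,
#'   `"other"`
#' @param diet `"dii"` or `"fv_servings"`
#' @param time_degree degree of the raw polynomial in the interval index
#'   (1-3; default quadratic)
#' @param exposure_terms log2 exposure columns, mutually adjusted
#' @param covariate_terms adjustment-set terms (formula syntax)
#' @param interactions include metal-by-diet product terms?
#' @param weight_col survey weight column name
#' @return an object of class `hazard_model_spec`
#' @export
hazard_model_spec <- function(cause = c("all", "cvd", "cancer", "other"),
                              diet = c("dii", "fv_servings"),
                              time_degree = 2L,
                              exposure_terms = c("lead_log2", "ucd_creat_log2"),
                              covariate_terms = default_covariate_terms(),
                              interactions = TRUE,
                              weight_col = "survey_weight") {
  cause <- match.arg(cause)
  diet <- match.arg(diet)
  stopifnot(time_degree %in% 1:3)
  structure(list(cause = cause, diet = diet,
                 time_degree = as.integer(time_degree),
                 exposure_terms = exposure_terms,
                 covariate_terms = covariate_terms,
                 interactions = isTRUE(interactions),
                 weight_col = weight_col),
            class = "hazard_model_spec")
}

#' @rdname hazard_model_spec
#' @export
default_covariate_terms <- function() {
  c("age", "sex", "ethnicity", "factor(poverty_income_tertile)",
    "education_years", "residence", "smoking", "bmi", "physical_activity")
}

# Model formula implied by a spec.
spec_formula <- function(spec) {
  time_terms <- c("t", "I(t^2)", "I(t^3)")[seq_len(spec$time_degree)]
  ix <- if (spec$interactions)
    paste0(spec$exposure_terms, ":", spec$diet) else character(0)
  rhs <- c(time_terms, spec$exposure_terms, spec$diet, ix,
           spec$covariate_terms)
  stats::as.formula(paste("event ~", paste(rhs, collapse = " + ")))
}

# Build the design matrix for a spec on arbitrary data; `xlev` pins factor
# levels for prediction on modified cohorts.
build_design <- function(data, spec, xlev = NULL) {
  f <- spec_formula(spec)
  tt <- stats::terms(f)
  mf <- stats::model.frame(tt, data = data, xlev = xlev,
                           na.action = stats::na.fail)
  list(X = stats::model.matrix(tt, mf),
       y = if ("event" %in% names(data)) stats::model.response(mf) else NULL,
       xlevels = stats::.getXlevels(tt, mf),
       terms = tt)
}

# Weighted logistic IRLS via stats::glm.fit (quasi family so non-integer
# survey weights do not trigger spurious warnings). `start` warm-starts
# the IRLS, which roughly halves bootstrap refit cost.
fit_glm_matrix <- function(X, y, w, start = NULL, epsilon = 1e-10) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, weights = w, family = stats::quasibinomial(),
                   start = start,
                   control = stats::glm.control(epsilon = epsilon, maxit = 50)))
  if (!fit$converged)
    stop("pooled logistic fit did not converge after ", fit$iter,
         " IRLS iterations")
  if (fit$rank < ncol(X)) {
    aliased <- colnames(X)[fit$qr$pivot[(fit$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(aliased, collapse = ", "))
  }
  if (any(abs(fit$coefficients) > 1e3))
    stop("implausibly large coefficient(s) -- possible separation: ",
         paste(names(fit$coefficients)[abs(fit$coefficients) > 1e3],
               collapse = ", "))
  fit
}

# Robust (sandwich) coefficient covariance for a survey-weighted logistic
# fit: A^-1 B A^-1 with A the weighted information and B the variance of
# the weighted score, sum_i w_i^2 v_i x_i x_i'. With heterogeneous survey
# weights the naive frequency-weight information underestimates the
# event-realization variance by roughly the factor 1 + CV(w)^2.
sandwich_vcov <- function(X, w, mu) {
  v <- mu * (1 - mu)
  A <- crossprod(X, X * (w * v))
  B <- crossprod(X, X * (w^2 * v))
  Ainv <- solve(A)
  V <- Ainv %*% B %*% Ainv
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

#' Fit a survey-weighted pooled logistic hazard model
#'
#' Maximizes the weighted Bernoulli log-likelihood over person-time rows
#' (weights treated as frequency-style weights in the estimating
#' equations); coefficient standard errors and covariance use the robust
#' sandwich form appropriate for survey weights. Non-convergence,
#' separation, and rank deficiency are errors.
#'
#' @param pt a person-time table from [expand_person_time()]
#' @param spec a [hazard_model_spec()]
#' @return an object of class `fitted_hazard_model` with named
#'   coefficients, robust `se` and `vcov`, convergence diagnostics, and
#'   the spec it was fitted under
#' @export
fit_pooled_logistic <- function(pt, spec = hazard_model_spec()) {
  stopifnot(inherits(spec, "hazard_model_spec"))
  if (sum(pt$event) < 1) stop("no events for the selected cause")
  d <- build_design(pt, spec)
  w <- pt[[spec$weight_col]]
  if (is.null(w)) stop("missing weight column: ", spec$weight_col)
  fit <- fit_glm_matrix(d$X, d$y, w)
  V <- sandwich_vcov(d$X, w, fit$fitted.values)
  structure(list(coefficients = fit$coefficients,
                 se = sqrt(diag(V)), vcov = V,
                 spec = spec,
                 xlevels = d$xlevels, converged = fit$converged,
                 iter = fit$iter, n_events = sum(pt$event),
                 n_rows = nrow(pt), deviance = fit$deviance),
            class = "fitted_hazard_model")
}

#' @export
print.fitted_hazard_model <- function(x, ...) {
  cat("Pooled logistic hazard model (", x$spec$cause, " mortality, diet = ",
      x$spec$diet, ")\n", sep = "")
  cat("  person-time rows:", x$n_rows, " events:", x$n_events, "\n")
  cat("  converged in", x$iter, "IRLS iterations\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Cumulative risk from per-interval hazards
#'
#' `1 - prod(1 - h_t)`: the discrete-time identity linking per-interval
#' hazards to cumulative incidence. Monotone non-decreasing in every
#' hazard and in the horizon.
#'
#' @param hazards per-interval hazard probabilities, each in [0, 1]
#' @return cumulative risk (scalar)
#' @export
#' @examples
#' cumulative_risk(rep(0.1, 3))  # 0.271
cumulative_risk <- function(hazards) {
  if (any(hazards < 0 | hazards > 1)) stop("hazards must lie in [0, 1]")
  1 - prod(1 - hazards)
}

# Recompute log2 exposure columns after an intervention has modified the
# natural-scale values.
refresh_exposure_transforms <- function(cohort) {
  cohort$lead_log2 <- log2_exposure(cohort$blood_lead)
  cohort$ucd_creat_log2 <- log2_exposure(cohort$ucd_creat)
  cohort
}

#' Model-based counterfactual risk for one scenario
#'
#' Applies the intervention to the cohort, re-derives the transformed
#' exposure columns, predicts each participant's per-interval hazards for
#' t = 1..horizon from the fitted model (baseline covariates fixed; only
#' the time terms vary), converts them to a per-participant cumulative
#' risk, and returns the survey-weighted mean. Deterministic given the
#' model and cohort.
#'
#' @param model a [fit_pooled_logistic()] fit
#' @param cohort the prepared cohort (one row per participant)
#' @param iv an [intervention()]
#' @param config a [prep_config()] supplying the horizon
#' @return the weighted 27-year cumulative risk (scalar); the resolved
#'   intervention cutoffs are attached as attribute `"targets"`
#' @export
estimate_scenario_risk <- function(model, cohort, iv = intervention("natural_course"),
                                   config = prep_config()) {
  stopifnot(inherits(model, "fitted_hazard_model"))
  spec <- model$spec
  cohort2 <- apply_intervention(cohort, iv,
                                weights = cohort[[spec$weight_col]])
  targets <- attr(cohort2, "targets")
  cohort2 <- refresh_exposure_transforms(cohort2)
  cohort2$t <- 0
  cohort2$event <- 0
  d <- build_design(cohort2, spec, xlev = model$xlevels)
  beta <- model$coefficients
  lp0 <- drop(d$X %*% beta)
  if (any(abs(lp0) > 30))
    warning(sum(abs(lp0) > 30), " participant(s) with extreme linear ",
            "predictors; hazards clipped by the logistic link")
  tt <- seq_len(config$horizon_years)
  time_lp <- beta[["t"]] * tt
  if (spec$time_degree >= 2L) time_lp <- time_lp + beta[["I(t^2)"]] * tt^2
  if (spec$time_degree >= 3L) time_lp <- time_lp + beta[["I(t^3)"]] * tt^3
  h <- stats::plogis(outer(lp0, time_lp, `+`))
  risk_i <- 1 - surv_from_hazards(h)
  w <- cohort[[spec$weight_col]]
  structure(sum(w * risk_i) / sum(w), targets = targets)
}

#' Delta-method standard error of a scenario risk
#'
#' Propagates the sampling variance of the fitted hazard coefficients
#' (binomial information) through the counterfactual standardization:
#' `se = sqrt(g' V g)` where `g` is the gradient of the weighted risk with
#' respect to the coefficient vector. Used as the estimator-side
#' uncertainty when validating against the simulation oracle; it reflects
#' event-realization noise, not the survey-design variance.
#'
#' @inheritParams estimate_scenario_risk
#' @param vcov_beta coefficient covariance matrix of the fit
#' @keywords internal
scenario_risk_se <- function(model, cohort, iv, config, vcov_beta) {
  spec <- model$spec
  cohort2 <- apply_intervention(cohort, iv,
                                weights = cohort[[spec$weight_col]])
  cohort2 <- refresh_exposure_transforms(cohort2)
  cohort2$t <- 0
  cohort2$event <- 0
  d <- build_design(cohort2, spec, xlev = model$xlevels)
  beta <- model$coefficients
  lp0 <- drop(d$X %*% beta)
  tt <- seq_len(config$horizon_years)
  time_lp <- beta[["t"]] * tt
  if (spec$time_degree >= 2L) time_lp <- time_lp + beta[["I(t^2)"]] * tt^2
  if (spec$time_degree >= 3L) time_lp <- time_lp + beta[["I(t^3)"]] * tt^3
  h <- stats::plogis(outer(lp0, time_lp, `+`))
  S <- surv_from_hazards(h)
  # d risk_i / d beta_j = S_i * sum_t h_it * x_ijt  (the dh/dbeta factor
  # h(1-h) is divided by the survival term's 1-h); x is constant over t
  # for non-time columns, t^k for the time columns
  a0 <- rowSums(h)
  G <- d$X * (S * a0)
  for (k in seq_len(spec$time_degree)) {
    cn <- c("t", "I(t^2)", "I(t^3)")[k]
    G[, cn] <- S * drop(h %*% tt^k)
  }
  w <- cohort[[spec$weight_col]]
  g <- colSums(G * w) / sum(w)
  sqrt(drop(t(g) %*% vcov_beta %*% g))
}

#' Risk ratio and risk difference of two scenario risks
#'
#' @param risk_intervened,risk_reference cumulative risks (proportions)
#' @return list with `rr` (ratio) and `rd_pts` (percentage points)
#' @export
contrast <- function(risk_intervened, risk_reference) {
  stopifnot(risk_intervened >= 0, risk_intervened <= 1,
            risk_reference >= 0, risk_reference <= 1)
  rr <- if (risk_reference > 0) risk_intervened / risk_reference else {
    warning("zero reference risk: RR undefined")
    NA_real_
  }
  list(rr = rr, rd_pts = (risk_intervened - risk_reference) * 100)
}

#' Nonparametric bootstrap percentile confidence intervals
#'
#' Resamples participants with replacement (whole-person resampling,
#' weights carried along), re-evaluates a statistic on each replicate, and
#' returns the 2.5th and 97.5th percentiles of each component.
#' Deterministic given the seed. Replicates on which the statistic errors
#' (e.g. a non-converging refit) are dropped and logged; more than 10%
#' failures is an error.
#'
#' @param statistic function of `(cohort_replicate, idx)` returning a named
#'   numeric vector; `idx` gives the resampled participant row indices for
#'   implementations that use precomputed structures
#' @param cohort the cohort to resample (one row per participant)
#' @param M number of bootstrap replicates (>= 2)
#' @param seed integer root seed; each replicate uses a derived substream
#' @param probs CI percentiles
#' @return list with `lower`, `upper` (named vectors), `replicates`
#'   (matrix, failed rows removed), `n_failed`, `M`
#' @export
bootstrap_ci <- function(statistic, cohort, M = 200, seed = 1,
                         probs = c(0.025, 0.975)) {
  stopifnot(M >= 2)
  n <- nrow(cohort)
  reps <- vector("list", M)
  failures <- character(0)
  for (m in seq_len(M)) {
    idx <- with_substream(substream_seed(seed, paste0("boot", m)),
                          sample.int(n, n, replace = TRUE))
    reps[[m]] <- tryCatch(
      statistic(cohort[idx, , drop = FALSE], idx),
      error = function(e) {
        failures <<- c(failures, conditionMessage(e))
        NULL
      })
  }
  ok <- !vapply(reps, is.null, logical(1))
  if (sum(!ok) > 0.10 * M)
    stop("more than 10% of bootstrap replicates failed; first error: ",
         failures[1])
  R <- do.call(rbind, reps[ok])
  list(lower = apply(R, 2, stats::quantile, probs = probs[1], na.rm = TRUE),
       upper = apply(R, 2, stats::quantile, probs = probs[2], na.rm = TRUE),
       replicates = R, n_failed = sum(!ok), M = M)
}

# ---- full pipeline ---------------------------------------------------------

# Precompute the person-time design for one cause on the full cohort, with
# per-participant row blocks so bootstrap replicates are assembled by
# indexing instead of re-expansion.
prep_fit_data <- function(cohort, spec, config) {
  pt <- expand_person_time(cohort, config, spec$cause)
  d <- build_design(pt, spec)
  n_int <- pmin(as.integer(ceiling(cohort$followup_years)),
                config$horizon_years)
  ends <- cumsum(n_int)
  starts <- ends - n_int + 1L
  list(X = d$X, y = d$y, w = pt[[spec$weight_col]],
       starts = starts, ends = ends,
       xlevels = d$xlevels)
}

# Point-estimate risks for every scenario given a fitted model.
scenario_risks <- function(fit, cohort, scenarios, config) {
  vapply(scenarios, function(iv)
    as.numeric(estimate_scenario_risk(fit, cohort, iv, config)), numeric(1))
}

# Named statistic vector (risks + contrasts) used for both the point
# estimate and each bootstrap replicate.
gf_statistics <- function(risks, references) {
  out <- stats::setNames(as.list(risks), paste0("risk.", names(risks)))
  for (ref in references) {
    for (sc in names(risks)) {
      ct <- contrast(risks[[sc]], risks[[ref]])
      out[[paste0("rr.", sc, ".vs.", ref)]] <- ct$rr
      out[[paste0("rd.", sc, ".vs.", ref)]] <- ct$rd_pts
    }
  }
  unlist(out)
}

#' Run the full g-formula analysis
#'
#' Orchestrates, per cause: person-time expansion, the pooled logistic
#' fit, counterfactual scenario risks, risk ratio / risk difference
#' contrasts against the natural course and (when a scenario named
#' `worst_case` is present) against the worst case, and bootstrap
#' percentile confidence intervals. A `natural_course` scenario is added
#' automatically if absent.
#'
#' @param cohort a prepared cohort (see [prepare_cohort()] and
#'   [score_diet()])
#' @param scenarios named list of [intervention()]s; defaults to
#'   [default_scenarios()] for the spec's diet exposure
#' @param spec a [hazard_model_spec()]; its `cause` field is overridden by
#'   `causes`
#' @param causes causes to analyse
#' @param M bootstrap replicates (`M = 0` skips the bootstrap)
#' @param seed integer root seed for the bootstrap
#' @param config a [prep_config()]
#' @return a data frame with one row per (cause, scenario, reference):
#'   columns `cause`, `scenario`, `reference`, `risk`, `rr`, `rr_lo`,
#'   `rr_hi`, `rd_pts`, `rd_lo`, `rd_hi`, `M`, `seed`. When a bootstrap
#'   was run, the per-cause replicate matrices are attached as attribute
#'   `"bootstrap_replicates"`.
#' @export
run_gformula <- function(cohort,
                         scenarios = NULL,
                         spec = hazard_model_spec(),
                         causes = c("all", "cvd", "cancer"),
                         M = 200, seed = 1,
                         config = prep_config()) {
  stopifnot(inherits(spec, "hazard_model_spec"))
  if (is.null(scenarios)) scenarios <- default_scenarios(spec$diet)
  nm <- vapply(scenarios, `[[`, character(1), "name")
  names(scenarios) <- nm
  if (!"natural_course" %in% nm)
    scenarios <- c(list(natural_course = intervention("natural_course")),
                   scenarios)
  references <- intersect(c("natural_course", "worst_case"),
                          names(scenarios))
  out <- list()
  reps_by_cause <- list()
  for (cz in causes) {
    spec_c <- spec
    spec_c$cause <- cz
    fd <- prep_fit_data(cohort, spec_c, config)
    fit0 <- fit_glm_matrix(fd$X, fd$y, fd$w)
    fit_obj <- structure(list(coefficients = fit0$coefficients,
                              spec = spec_c, xlevels = fd$xlevels,
                              converged = TRUE, iter = fit0$iter,
                              n_events = sum(fd$y), n_rows = length(fd$y)),
                         class = "fitted_hazard_model")
    point <- gf_statistics(scenario_risks(fit_obj, cohort, scenarios, config),
                           references)
    ci <- NULL
    if (M >= 2) {
      statistic <- function(cohort_b, idx) {
        rows <- sequence(fd$ends[idx] - fd$starts[idx] + 1L,
                         from = fd$starts[idx])
        fit_b <- fit_glm_matrix(fd$X[rows, , drop = FALSE], fd$y[rows],
                                fd$w[rows], start = fit0$coefficients,
                                epsilon = 1e-8)
        fb <- fit_obj
        fb$coefficients <- fit_b$coefficients
        gf_statistics(scenario_risks(fb, cohort_b, scenarios, config),
                      references)
      }
      ci <- bootstrap_ci(statistic, cohort, M = M,
                         seed = substream_seed(seed, paste0("cause_", cz)))
      reps_by_cause[[cz]] <- ci$replicates
    }
    for (ref in references) {
      for (sc in names(scenarios)) {
        key_rr <- paste0("rr.", sc, ".vs.", ref)
        key_rd <- paste0("rd.", sc, ".vs.", ref)
        out[[length(out) + 1L]] <- data.frame(
          cause = cz, scenario = sc, reference = ref,
          risk = unname(point[[paste0("risk.", sc)]]),
          rr = unname(point[[key_rr]]),
          rr_lo = if (is.null(ci)) NA_real_ else unname(ci$lower[[key_rr]]),
          rr_hi = if (is.null(ci)) NA_real_ else unname(ci$upper[[key_rr]]),
          rd_pts = unname(point[[key_rd]]),
          rd_lo = if (is.null(ci)) NA_real_ else unname(ci$lower[[key_rd]]),
          rd_hi = if (is.null(ci)) NA_real_ else unname(ci$upper[[key_rd]]),
          M = M, seed = seed,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "bootstrap_replicates") <- reps_by_cause
  res
}
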