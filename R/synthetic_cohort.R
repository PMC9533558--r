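# Synthetic cohort generator with a fully known discrete-time hazard model,
# and a brute-force Monte-Carlo counterfactual oracle.
#
# The generator emulates the statistical structure of a US adult survey
# cohort: right-skewed metal exposures correlated with age, sex and
# smoking; 24 dietary component intakes conditional on energy plus coded
# fruit/vegetable records; heterogeneous survey weights; and mortality
# simulated year by year from three cause-specific logistic hazards
# (cardiovascular, cancer, other) with metal and diet main effects and
# metal-by-diet interactions, administratively censored at 27 years.

#' Construct the true data-generating hazard model
#'
#' Defines the per-cause discrete-time logistic hazards
#' `logit h_c(t) = a_c + g1_c t + g2_c t^2 + covariate terms + exposure
#' terms`, where the exposure terms are
#' `b_lead * log2(lead) + b_cad * log2(ucd) + b_dii * DII + b_fv * FV`
#' plus the four metal-by-diet products. Exposure coefficients are shared
#' across causes; intercepts and time trends are cause-specific.
#' Covariate terms use centered codings (age per 10 years about 48, BMI per
#' 5 kg/m2 about 27, education per year about 11, indicator contrasts
#' otherwise) so the intercepts are interpretable at a reference profile.
#'
#' @param causes named list (`cvd`, `cancer`, `other`) of lists with
#'   `intercept`, `t1`, `t2` (logit scale, per year / per year^2)
#' @param beta_lead,beta_cadmium logit per doubling of blood lead / UCd
#' @param beta_dii logit per unit of the inflammatory index (positive
#'   score = anti-inflammatory, so a protective diet has negative beta)
#' @param beta_fv logit per daily fruit-and-vegetable serving
#' @param beta_ix named numeric: `lead_dii`, `cadmium_dii`, `lead_fv`,
#'   `cadmium_fv` product-term coefficients
#' @param covariate_effects named numeric of covariate logit coefficients
#' @param exposure_distribution log-normal location/scale and covariate
#'   shifts for lead (ug/dL), creatinine-corrected cadmium (ug/g) and
#'   urinary creatinine (g/L)
#' @param lod_lead blood lead detection limit (ug/dL)
#' @param max_followup_years administrative horizon (years)
#' @return an object of class `true_model`
#' @export
true_model <- function(causes = default_cause_params(),
                       beta_lead = 0.15, beta_cadmium = 0.20,
                       beta_dii = -0.05, beta_fv = -0.04,
                       beta_ix = c(lead_dii = -0.02, cadmium_dii = -0.02,
                                   lead_fv = -0.01, cadmium_fv = -0.01),
                       covariate_effects = default_covariate_effects(),
                       exposure_distribution = default_exposure_distribution(),
                       lod_lead = 1.0,
                       max_followup_years = 27L) {
  stopifnot(all(c("cvd", "cancer", "other") %in% names(causes)),
            max_followup_years >= 1,
            all(c("lead_dii", "cadmium_dii", "lead_fv", "cadmium_fv")
                %in% names(beta_ix)),
            exposure_distribution$lead$sdlog > 0,
            exposure_distribution$cadmium$sdlog > 0,
            lod_lead > 0)
  for (b in c(beta_lead, beta_cadmium, beta_dii, beta_fv, beta_ix,
              unlist(covariate_effects)))
    stopifnot(is.finite(b))
  structure(list(causes = causes, beta_lead = beta_lead,
                 beta_cadmium = beta_cadmium, beta_dii = beta_dii,
                 beta_fv = beta_fv, beta_ix = beta_ix,
                 covariate_effects = covariate_effects,
                 exposure_distribution = exposure_distribution,
                 lod_lead = lod_lead,
                 max_followup_years = as.integer(max_followup_years)),
            class = "true_model")
}

#' @rdname true_model
#' @export
default_cause_params <- function() {
  # Intercepts calibrated once by simulation so the default cohort shows a
  # 27-year all-cause risk near 36% with roughly 30% of deaths
  # cardiovascular and 22% cancer; hazards rise with follow-up time.
  list(cvd    = list(intercept = -7.20, t1 = 0.07, t2 = 0),
       cancer = list(intercept = -7.49, t1 = 0.07, t2 = 0),
       other  = list(intercept = -6.75, t1 = 0.07, t2 = 0))
}

#' @rdname true_model
#' @export
default_covariate_effects <- function() {
  c(age10 = 0.75, male = 0.35,
    eth_mexican_american = -0.05, eth_other_hispanic = -0.05,
    pov_t1 = 0.20, pov_t2 = 0.08, education_year = -0.02,
    res_nonmetro = 0.05, smoke_current = 0.55, smoke_former = 0.15,
    bmi5 = 0.10, act_none = 0.30, act_low = 0.12)
}

#' @rdname true_model
#' @export
default_exposure_distribution <- function() {
  list(
    lead = list(meanlog = log(2.97), sdlog = 0.60,
                shifts = c(age10 = 0.12, male = 0.55,
                           smoke_current = 0.45, smoke_former = 0.30,
                           diet_quality = 0.05)),
    cadmium = list(meanlog = log(0.36), sdlog = 0.70,
                   shifts = c(age10 = 0.30, male = -0.30,
                              smoke_current = 0.55, smoke_former = 0.45,
                              diet_quality = 0)),
    creatinine = list(meanlog = log(1.1), sdlog = 0.30)
  )
}

#' A matched single-cause model for estimator validation
#'
#' A variant of [true_model()] under which the analysis model is exactly
#' well specified, used to verify estimator consistency against the
#' simulation oracle: a single active cause (the competing-cause
#' intercepts are sent to -30, so ties never occur and the all-cause and
#' cause-specific hazards coincide), effects only for the diet exposure
#' the analysis model includes (a model fitted with one diet variable
#' would otherwise absorb part of the omitted diet effect), and a
#' negligible lead detection limit so below-LOD imputation does not
#' introduce measurement error into the comparison.
#'
#' @param diet the diet exposure of the analysis model to be validated
#' @param intercept baseline logit hazard of the active cause
#' @param beta_lead,beta_cadmium,beta_diet effect sizes (per doubling /
#'   per unit); `beta_diet` applies to the selected diet exposure
#' @param interactions metal-by-diet product coefficients (length 2:
#'   lead and cadmium)
#' @return a `true_model`
#' @export
validation_true_model <- function(diet = c("dii", "fv_servings"),
                                  intercept = -6.2,
                                  beta_lead = 0.15, beta_cadmium = 0.20,
                                  beta_diet = if (diet == "dii") -0.05 else -0.04,
                                  interactions = c(-0.02, -0.02)) {
  diet <- match.arg(diet)
  cp <- default_cause_params()
  cp$cvd$intercept <- intercept
  cp$cancer$intercept <- -30
  cp$other$intercept <- -30
  ix <- c(lead_dii = 0, cadmium_dii = 0, lead_fv = 0, cadmium_fv = 0)
  if (diet == "dii") {
    ix[c("lead_dii", "cadmium_dii")] <- interactions
    bd <- c(dii = beta_diet, fv = 0)
  } else {
    ix[c("lead_fv", "cadmium_fv")] <- interactions
    bd <- c(dii = 0, fv = beta_diet)
  }
  true_model(causes = cp, beta_lead = beta_lead, beta_cadmium = beta_cadmium,
             beta_dii = bd[["dii"]], beta_fv = bd[["fv"]], beta_ix = ix,
             lod_lead = 0.05)
}

#' Configuration of a synthetic cohort draw
#'
#' @param n_participants number of participants (> 0)
#' @param seed integer root seed; every substream is derived from it
#' @param weight_dispersion coefficient of variation of the log-normal
#'   survey weights (0 gives equal weights)
#' @param missingness_rate fraction of participants given one missing
#'   covariate or vital-status field, to exercise exclusion filters
#' @param censor_range administrative censoring drawn uniformly from this
#'   range (years); the default censors every survivor at the horizon
#' @return an object of class `cohort_config`
#' @export
cohort_config <- function(n_participants, seed, weight_dispersion = 0.6,
                          missingness_rate = 0, censor_range = c(27, 27)) {
  stopifnot(is.finite(n_participants), n_participants > 0,
            is.finite(seed), weight_dispersion >= 0,
            missingness_rate >= 0, missingness_rate < 1,
            length(censor_range) == 2L, censor_range[1] <= censor_range[2],
            censor_range[1] > 0)
  structure(list(n_participants = as.integer(n_participants),
                 seed = as.integer(seed),
                 weight_dispersion = weight_dispersion,
                 missingness_rate = missingness_rate,
                 censor_range = censor_range),
            class = "cohort_config")
}

# Centered covariate design used by the true hazard model. Returns the
# n-vector of covariate logit contributions.
true_cov_lp <- function(model, d) {
  ce <- model$covariate_effects
  ce[["age10"]] * (d$age - 48) / 10 +
    ce[["male"]] * (d$sex == "male") +
    ce[["eth_mexican_american"]] * (d$ethnicity == "mexican_american") +
    ce[["eth_other_hispanic"]] * (d$ethnicity == "other_hispanic") +
    ce[["pov_t1"]] * (d$poverty_income_tertile == 1) +
    ce[["pov_t2"]] * (d$poverty_income_tertile == 2) +
    ce[["education_year"]] * (d$education_years - 11) +
    ce[["res_nonmetro"]] * (d$residence == "nonmetro") +
    ce[["smoke_current"]] * (d$smoking == "current") +
    ce[["smoke_former"]] * (d$smoking == "former") +
    ce[["bmi5"]] * (d$bmi - 27) / 5 +
    ce[["act_none"]] * (d$physical_activity == "none") +
    ce[["act_low"]] * (d$physical_activity == "1_14")
}

# Exposure + diet + interaction logit contributions from natural-scale
# exposures (lead ug/dL, ucd ug/g) and diet scores.
true_exposure_lp <- function(model, lead, ucd_creat, dii, fv) {
  L <- log2(lead)
  C <- log2(ucd_creat)
  model$beta_lead * L + model$beta_cadmium * C +
    model$beta_dii * dii + model$beta_fv * fv +
    model$beta_ix[["lead_dii"]] * L * dii +
    model$beta_ix[["cadmium_dii"]] * C * dii +
    model$beta_ix[["lead_fv"]] * L * fv +
    model$beta_ix[["cadmium_fv"]] * C * fv
}

# Per-cause hazard matrix (rows = participants, cols = causes) at year t,
# given the time-constant part of each cause's linear predictor.
hazard_at_t <- function(model, base_lp, t) {
  cs <- model$causes
  cbind(
    cvd = stats::plogis(base_lp[, 1L] + cs$cvd$t1 * t + cs$cvd$t2 * t^2),
    cancer = stats::plogis(base_lp[, 2L] + cs$cancer$t1 * t + cs$cancer$t2 * t^2),
    other = stats::plogis(base_lp[, 3L] + cs$other$t1 * t + cs$other$t2 * t^2)
  )
}

# Time-constant per-cause linear predictors for a cohort (or for supplied
# exposure vectors, when an intervention has modified them).
true_base_lp <- function(model, d, lead = NULL, ucd = NULL,
                         dii = NULL, fv = NULL) {
  lead <- lead %||% d$blood_lead
  ucd <- ucd %||% (if (!is.null(d$ucd_creat)) d$ucd_creat
                   else d$urinary_cadmium / d$urinary_creatinine)
  dii <- dii %||% d$dii
  fv <- fv %||% d$fv_servings
  shared <- true_cov_lp(model, d) +
    true_exposure_lp(model, lead, ucd, dii, fv)
  cbind(model$causes$cvd$intercept + shared,
        model$causes$cancer$intercept + shared,
        model$causes$other$intercept + shared)
}

# Simulate death year and cause from the true hazards. base_lp is N x 3;
# returns list(year, cause_idx) with cause_idx 0 for survivors beyond the
# horizon. Causes whose hazard draws fire in the same year are resolved by
# the smallest uniform draw.
simulate_deaths <- function(model, base_lp, horizon = model$max_followup_years) {
  n <- nrow(base_lp)
  year <- rep(NA_integer_, n)
  cause_idx <- rep(0L, n)
  alive <- rep(TRUE, n)
  for (t in seq_len(horizon)) {
    if (!any(alive)) break
    h <- hazard_at_t(model, base_lp, t)
    u <- matrix(stats::runif(3L * n), n, 3L)
    fired <- (u < h) & alive
    dies <- rowSums(fired) > 0
    if (any(dies)) {
      u[!fired] <- Inf
      cause_idx[dies] <- max.col(-u[dies, , drop = FALSE], ties.method = "first")
      year[dies] <- t
      alive[dies] <- FALSE
    }
  }
  list(year = year, cause_idx = cause_idx)
}

#' Generate a synthetic cohort
#'
#' Draws covariates, exposures, diet, survey weights and simulated
#' follow-up for `n_participants` adults from the supplied true model.
#' Identical `(config, model)` pairs yield identical tables. Blood lead is
#' stored at its TRUE value with a `lead_below_lod` flag; downstream
#' preparation decides how to handle censored values. DII and FV-serving
#' columns are computed from the generated dietary data with the default
#' registries (so the stored scores are exactly what the scoring module
#' produces).
#'
#' @param config a [cohort_config()]
#' @param model a [true_model()]
#' @return a cohort data frame (one row per participant)
#' @export
generate_cohort <- function(config, model = true_model()) {
  stopifnot(inherits(config, "cohort_config"), inherits(model, "true_model"))
  n <- config$n_participants
  seed <- config$seed

  d <- with_substream(substream_seed(seed, "covariates"), {
    data.frame(
      id = sprintf("P%07d", seq_len(n)),
      age = pmin(90, pmax(20, round(stats::rnorm(n, 48, 18), 1))),
      sex = sample(c("male", "female"), n, TRUE, c(0.471, 0.529)),
      ethnicity = sample(c("mexican_american", "other_hispanic", "not_hispanic"),
                         n, TRUE, c(0.272, 0.026, 0.702)),
      poverty_income_tertile = sample(1:3, n, TRUE),
      education_years = pmin(17, pmax(0, round(stats::rnorm(n, 11, 3.5)))),
      residence = sample(c("metro", "nonmetro"), n, TRUE, c(0.52, 0.48)),
      smoking = sample(c("never", "current", "former"), n, TRUE,
                       c(0.477, 0.313, 0.210)),
      bmi = round(pmin(60, pmax(15, stats::rnorm(n, 27, 5.5))), 1),
      physical_activity = sample(c("none", "1_14", "15_plus"), n, TRUE,
                                 c(0.205, 0.356, 0.439)),
      stringsAsFactors = FALSE
    )
  })

  # latent diet-quality factor ties anti-inflammatory intakes, FV records
  # and (weakly) exposures together
  q <- with_substream(substream_seed(seed, "diet_quality"),
                      stats::rnorm(n))

  ed <- model$exposure_distribution
  shift_lp <- function(sh) {
    sh[["age10"]] * (d$age - 48) / 10 +
      sh[["male"]] * ((d$sex == "male") - 0.471) +
      sh[["smoke_current"]] * ((d$smoking == "current") - 0.313) +
      sh[["smoke_former"]] * ((d$smoking == "former") - 0.210) +
      sh[["diet_quality"]] * q
  }
  expo <- with_substream(substream_seed(seed, "exposures"), {
    lead <- exp(ed$lead$meanlog + shift_lp(ed$lead$shifts) +
                  stats::rnorm(n, 0, ed$lead$sdlog))
    ucd_creat <- exp(ed$cadmium$meanlog + shift_lp(ed$cadmium$shifts) +
                       stats::rnorm(n, 0, ed$cadmium$sdlog))
    creat <- exp(ed$creatinine$meanlog +
                   stats::rnorm(n, 0, ed$creatinine$sdlog))
    list(lead = lead, ucd_creat = ucd_creat, creat = creat)
  })
  d$blood_lead <- round(expo$lead, 4)
  d$lead_below_lod <- d$blood_lead < model$lod_lead
  d$urinary_creatinine <- round(expo$creat, 4)
  d$urinary_cadmium <- round(expo$ucd_creat * expo$creat, 5)

  d <- with_substream(substream_seed(seed, "diet"),
                      cbind(d, generate_diet(n, d, q)))
  d$fv_records <- with_substream(substream_seed(seed, "fv"),
                                 generate_fv_records(n, q))

  d$survey_weight <- with_substream(substream_seed(seed, "weights"), {
    cv <- config$weight_dispersion
    if (cv == 0) rep(1, n) else {
      s2 <- log(1 + cv^2)
      w <- stats::rlnorm(n, -s2 / 2, sqrt(s2))
      w / mean(w)
    }
  })

  d <- score_diet(d)

  # survival from the true hazards, using the stored (true, uncensored)
  # exposure values so the oracle sees exactly the generating hazards
  base_lp <- true_base_lp(model, d)
  sim <- with_substream(substream_seed(seed, "survival"),
                        simulate_deaths(model, base_lp))
  censor <- with_substream(substream_seed(seed, "censoring"), {
    if (diff(config$censor_range) == 0)
      rep(config$censor_range[1], n)
    else round(stats::runif(n, config$censor_range[1],
                            config$censor_range[2]), 2)
  })
  censor <- pmin(censor, model$max_followup_years)
  died <- !is.na(sim$year) & sim$year <= censor
  d$followup_years <- ifelse(died, sim$year, censor)
  d$died <- died
  d$cause <- ifelse(died, c("cvd", "cancer", "other")[sim$cause_idx], "none")

  if (config$missingness_rate > 0) {
    d <- with_substream(substream_seed(seed, "missingness"),
                        inject_missingness(d, config$missingness_rate))
  }
  rownames(d) <- NULL
  d
}

# 24 dietary component intakes drawn log-normal conditional on energy,
# with anti-inflammatory components loading positively on the latent diet
# quality factor q. Base intakes approximate typical adult daily amounts
# at 2000 kcal (component-native units/day).
generate_diet <- function(n, d, q) {
  base <- c(carbohydrate = 250, protein = 80, alcohol = 5, fiber = 16,
            cholesterol = 290, saturated_fat = 26, monounsaturated_fat = 30,
            omega3 = 1.5, omega6 = 14, niacin = 24, thiamin = 1.7,
            riboflavin = 2, vitamin_b6 = 2, vitamin_b12 = 5, iron = 15,
            magnesium = 300, zinc = 12, vitamin_a = 900, vitamin_c = 90,
            vitamin_d = 5, vitamin_e = 9, folic_acid = 350,
            beta_carotene = 2500, caffeine = 180)
  sdlog <- c(carbohydrate = 0.25, protein = 0.3, alcohol = 1.2, fiber = 0.4,
             cholesterol = 0.5, saturated_fat = 0.35,
             monounsaturated_fat = 0.35, omega3 = 0.5, omega6 = 0.4,
             niacin = 0.35, thiamin = 0.35, riboflavin = 0.35,
             vitamin_b6 = 0.35, vitamin_b12 = 0.6, iron = 0.35,
             magnesium = 0.3, zinc = 0.35, vitamin_a = 0.6, vitamin_c = 0.7,
             vitamin_d = 0.7, vitamin_e = 0.45, folic_acid = 0.4,
             beta_carotene = 0.8, caffeine = 0.9)
  # anti-inflammatory components rise with q, pro-inflammatory fall
  loading <- c(carbohydrate = -0.05, protein = 0, alcohol = 0, fiber = 0.25,
               cholesterol = -0.2, saturated_fat = -0.25,
               monounsaturated_fat = 0.05, omega3 = 0.25, omega6 = 0.1,
               niacin = 0.1, thiamin = 0.1, riboflavin = 0.1,
               vitamin_b6 = 0.15, vitamin_b12 = 0, iron = 0.05,
               magnesium = 0.2, zinc = 0.1, vitamin_a = 0.2,
               vitamin_c = 0.3, vitamin_d = 0.15, vitamin_e = 0.2,
               folic_acid = 0.2, beta_carotene = 0.3, caffeine = 0)
  energy <- exp(log(2000) + 0.15 * (d$sex == "male") -
                  0.002 * (d$age - 48) + stats::rnorm(n, 0, 0.28))
  out <- data.frame(diet_energy_kcal = round(energy, 1))
  for (comp in names(base)) {
    x <- base[[comp]] * (energy / 2000) *
      exp(loading[[comp]] * q + stats::rnorm(n, 0, sdlog[[comp]]))
    out[[paste0("diet_", comp)]] <- round(x, 4)
  }
  out
}

# Coded fruit/vegetable records: a Poisson number of items whose rate
# rises with diet quality; quantities are log-normal around one serving.
# A small fraction of records are excluded sweets.
generate_fv_records <- function(n, q) {
  reg <- default_serving_registry()
  fv_codes <- reg$food_code[reg$group != "excluded"]
  ex_codes <- reg$food_code[reg$group == "excluded"]
  sizes <- stats::setNames(reg$serving_size, reg$food_code)
  n_items <- stats::rpois(n, exp(log(3.0) + 0.30 * q))
  lapply(seq_len(n), function(i) {
    k <- n_items[i]
    if (k == 0L) return(data.frame(food_code = character(0),
                                   quantity = numeric(0)))
    excl <- stats::runif(k) < 0.10
    code <- ifelse(excl, sample(ex_codes, k, TRUE), sample(fv_codes, k, TRUE))
    size <- ifelse(is.na(sizes[code]), 100, sizes[code])
    data.frame(food_code = code,
               quantity = round(size * stats::rlnorm(k, 0, 0.45), 1),
               stringsAsFactors = FALSE)
  })
}

# Blank out one analysis field for a random subset of participants.
inject_missingness <- function(d, rate) {
  n <- nrow(d)
  n_miss <- floor(rate * n)
  if (n_miss == 0L) return(d)
  rows <- sample.int(n, n_miss)
  fields <- sample(c(adjustment_columns(), "died"), n_miss, TRUE)
  for (k in seq_len(n_miss)) d[rows[k], fields[k]] <- NA
  d
}

#' Brute-force counterfactual risk from the true model
#'
#' Applies an intervention to the cohort's exposures and simulates `n_reps`
#' survival trajectories per participant from the TRUE hazards, returning
#' the survey-weighted 27-year cumulative incidence of the selected cause
#' together with its Monte-Carlo standard error. This is the ground truth
#' against which the g-formula estimator is validated.
#'
#' @param model the [true_model()] that generated `cohort`
#' @param cohort a generated cohort
#' @param iv an [intervention()] (empty rules = natural course)
#' @param cause `"all"`, `"cvd"`, `"cancer"` or `"other"`
#' @param n_reps simulated trajectories per participant
#' @param seed integer seed
#' @param net for a specific cause, simulate with the competing causes
#'   switched off, returning the net (competing-risk-eliminated) risk --
#'   the quantity targeted by a cause-specific hazard model with
#'   cause-specific censoring. The default (`FALSE`) keeps competing
#'   causes active and returns the crude cumulative incidence.
#' @return list with `risk`, `mc_se`, `n_reps`
#' @export
oracle_counterfactual_risk <- function(model, cohort, iv,
                                       cause = c("all", "cvd", "cancer", "other"),
                                       n_reps = 100, seed = 1, net = FALSE) {
  cause <- match.arg(cause)
  stopifnot(inherits(model, "true_model"), n_reps >= 1)
  if (net && cause != "all") model <- switch_off_competing(model, cause)
  x <- oracle_exposures(model, cohort, iv)
  base_lp <- true_base_lp(model, cohort, lead = x$blood_lead,
                          ucd = x$ucd_creat, dii = x$dii, fv = x$fv_servings)
  n <- nrow(cohort)
  horizon <- model$max_followup_years
  hits <- with_substream(substream_seed(seed, "oracle"), {
    acc <- numeric(n)
    for (r in seq_len(n_reps)) {
      sim <- simulate_deaths(model, base_lp, horizon)
      dead <- !is.na(sim$year)
      sel <- if (cause == "all") dead
             else dead & (c("cvd", "cancer", "other")[pmax(sim$cause_idx, 1L)] ==
                            cause & sim$cause_idx > 0L)
      acc <- acc + sel
    }
    acc
  })
  p <- hits / n_reps
  u <- cohort$survey_weight / sum(cohort$survey_weight)
  list(risk = sum(u * p),
       mc_se = sqrt(sum(u^2 * p * (1 - p) / n_reps)),
       n_reps = n_reps)
}

# Disable the competing causes of `cause` by sending their intercepts to
# -Inf; their hazards are then exactly 0 at every age and time.
switch_off_competing <- function(model, cause) {
  for (cz in setdiff(c("cvd", "cancer", "other"), cause))
    model$causes[[cz]]$intercept <- -Inf
  model
}

# Resolve the intervened natural-scale exposures for the oracle; validates
# that all intervened variables exist in the true model's exposure set.
oracle_exposures <- function(model, cohort, iv) {
  stopifnot(inherits(iv, "intervention"))
  for (r in iv$rules) {
    if (!r$variable %in% INTERVENABLE)
      stop("intervention references a variable absent from the model: ",
           r$variable)
  }
  frame <- data.frame(
    blood_lead = cohort$blood_lead,
    ucd_creat = if (!is.null(cohort$ucd_creat)) cohort$ucd_creat
                else cohort$urinary_cadmium / cohort$urinary_creatinine,
    dii = cohort$dii,
    fv_servings = cohort$fv_servings,
    survey_weight = cohort$survey_weight
  )
  apply_intervention(frame, iv)
}

#' Exact counterfactual risk from the true model
#'
#' Closed-form counterpart of [oracle_counterfactual_risk()]: computes each
#' participant's cumulative incidence analytically from the true hazards
#' (accounting for the uniform tie-break when several cause hazards fire in
#' the same year) and returns the weighted mean. No Monte-Carlo error.
#'
#' @inheritParams oracle_counterfactual_risk
#' @return the weighted cumulative incidence (scalar)
#' @export
exact_counterfactual_risk <- function(model, cohort, iv,
                                      cause = c("all", "cvd", "cancer", "other"),
                                      net = FALSE) {
  cause <- match.arg(cause)
  if (net && cause != "all") model <- switch_off_competing(model, cause)
  x <- oracle_exposures(model, cohort, iv)
  base_lp <- true_base_lp(model, cohort, lead = x$blood_lead,
                          ucd = x$ucd_creat, dii = x$dii, fv = x$fv_servings)
  n <- nrow(cohort)
  horizon <- model$max_followup_years
  surv <- rep(1, n)
  ci <- numeric(n)
  for (t in seq_len(horizon)) {
    h <- hazard_at_t(model, base_lp, t)
    p_any <- 1 - (1 - h[, 1]) * (1 - h[, 2]) * (1 - h[, 3])
    p_t <- if (cause == "all") p_any else {
      j <- match(cause, c("cvd", "cancer", "other"))
      hc <- h[, j]
      ho <- h[, -j, drop = FALSE]
      hc * (1 - ho[, 1]) * (1 - ho[, 2]) +
        hc * (ho[, 1] * (1 - ho[, 2]) + ho[, 2] * (1 - ho[, 1])) / 2 +
        hc * ho[, 1] * ho[, 2] / 3
    }
    ci <- ci + surv * p_t
    surv <- surv * (1 - p_any)
  }
  u <- cohort$survey_weight / sum(cohort$survey_weight)
  sum(u * ci)
}
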