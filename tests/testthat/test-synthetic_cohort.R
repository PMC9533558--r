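# Synthetic cohort generator and counterfactual oracle.

test_that("generation is deterministic and respects config invariants", {
  cfg <- cohort_config(300, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 300L)
  expect_true(all(a$followup_years > 0))
  expect_true(all(a$followup_years <= 27))
  expect_true(all(a$survey_weight > 0))
  expect_identical(a$cause == "none", !a$died)
  expect_identical(a$lead_below_lod, a$blood_lead < 1.0)
  # a different seed changes the draw
  expect_false(identical(a, generate_cohort(cohort_config(300, seed = 8))))
})

test_that("config validation rejects out-of-range fields", {
  expect_error(cohort_config(0, 1))
  expect_error(cohort_config(10, 1, weight_dispersion = -1))
  expect_error(cohort_config(10, 1, missingness_rate = 1))
  expect_error(cohort_config(Inf, 1))
})

test_that("missingness injection feeds the exclusion filter", {
  cfg <- cohort_config(400, seed = 21, missingness_rate = 0.1)
  d <- generate_cohort(cfg)
  res <- apply_exclusions(d)
  expect_equal(attr(res$log, "n_input") - attr(res$log, "n_retained"),
               40L)
  expect_false(anyNA(res$cohort[, c(
    "followup_years", "died", "age", "sex", "smoking", "bmi")]))
})

test_that("null-effect model matches the closed-form baseline risk", {
  # all exposure, diet, interaction and covariate effects zero, flat time
  # trend: the per-year all-cause hazard is exactly the combination of the
  # three intercepts, and the 27-year risk has a closed form.
  cp <- list(cvd = list(intercept = -5.5, t1 = 0, t2 = 0),
             cancer = list(intercept = -5.8, t1 = 0, t2 = 0),
             other = list(intercept = -5.2, t1 = 0, t2 = 0))
  ce <- default_covariate_effects(); ce[] <- 0
  m <- true_model(causes = cp, beta_lead = 0, beta_cadmium = 0,
                  beta_dii = 0, beta_fv = 0,
                  beta_ix = c(lead_dii = 0, cadmium_dii = 0,
                              lead_fv = 0, cadmium_fv = 0),
                  covariate_effects = ce)
  n <- 1000
  d <- generate_cohort(cohort_config(n, seed = 7, weight_dispersion = 0), m)
  q_year <- 1 - (1 - plogis(-5.5)) * (1 - plogis(-5.8)) * (1 - plogis(-5.2))
  risk27 <- 1 - (1 - q_year)^27
  se <- sqrt(risk27 * (1 - risk27) / n)
  expect_lt(abs(mean(d$died) - risk27), 3 * se)
  # per-year event fraction among those at risk in year 1
  expect_lt(abs(mean(ceiling(d$followup_years) == 1 & d$died) - q_year),
            3 * sqrt(q_year * (1 - q_year) / n))
})

test_that("oracle identity run agrees with the closed form and causes close", {
  m <- true_model()
  d <- cached_cohort("small_default", 800, seed = 31)
  nc <- intervention("natural_course")
  mc <- oracle_counterfactual_risk(m, d, nc, "all", n_reps = 200, seed = 4)
  exact <- exact_counterfactual_risk(m, d, nc, "all")
  expect_lt(abs(mc$risk - exact), 3 * mc$mc_se + 1e-9)
  # competing-cause closure: same seed means identical trajectories, so
  # cause-specific crude risks partition the all-cause risk exactly
  parts <- vapply(c("cvd", "cancer", "other"), function(cz)
    oracle_counterfactual_risk(m, d, nc, cz, n_reps = 50, seed = 4)$risk,
    numeric(1))
  all_c <- oracle_counterfactual_risk(m, d, nc, "all", n_reps = 50, seed = 4)
  expect_equal(sum(parts), all_c$risk, tolerance = 1e-12)
  # exact closed form closes too
  exact_parts <- vapply(c("cvd", "cancer", "other"), function(cz)
    exact_counterfactual_risk(m, d, nc, cz), numeric(1))
  expect_equal(sum(exact_parts), exact, tolerance = 1e-12)
})

test_that("oracle lowers risk when capping a harmful exposure", {
  m <- true_model()
  d <- cached_cohort("small_default", 800, seed = 31)
  cap <- intervention("cap_lead", rule("blood_lead", "cap", percentile = 5))
  r_cap <- oracle_counterfactual_risk(m, d, cap, "all", n_reps = 500, seed = 9)
  r_nc <- oracle_counterfactual_risk(m, d, intervention("nc"), "all",
                                     n_reps = 500, seed = 9)
  expect_lt(r_cap$risk, r_nc$risk)
  # null-effect model: any intervention equals the natural course
  ce <- default_covariate_effects()
  m0 <- true_model(beta_lead = 0, beta_cadmium = 0, beta_dii = 0, beta_fv = 0,
                   beta_ix = c(lead_dii = 0, cadmium_dii = 0,
                               lead_fv = 0, cadmium_fv = 0),
                   covariate_effects = ce)
  r0_cap <- oracle_counterfactual_risk(m0, d, cap, "all", n_reps = 300, seed = 2)
  r0_nc <- oracle_counterfactual_risk(m0, d, intervention("nc"), "all",
                                      n_reps = 300, seed = 2)
  expect_identical(r0_cap$risk, r0_nc$risk)  # same hazards, same draws
  expect_error(oracle_counterfactual_risk(
    m, d, structure(list(name = "bad",
                         rules = list(structure(
                           list(variable = "ozone", mode = "cap",
                                percentile = NULL, value = 1),
                           class = "intervention_rule"))),
                    class = "intervention"),
    "all"), "ozone")
})

test_that("stored diet scores equal a recomputation from the diet columns", {
  d <- cached_cohort("small_default", 800, seed = 31)
  rescored <- score_diet(d[, setdiff(names(d), c("dii", "fv_servings"))])
  expect_equal(rescored$dii, d$dii)
  expect_equal(rescored$fv_servings, d$fv_servings)
})

test_that("cohort CSV and true-model YAML round-trip", {
  d <- cached_cohort("small_default", 800, seed = 31)[1:40, ]
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(d, f)
  back <- read_cohort_csv(f)
  expect_equal(back$blood_lead, d$blood_lead)
  expect_equal(back$dii, d$dii, tolerance = 1e-12)
  expect_equal(nrow(back), nrow(d))
  i <- which(vapply(d$fv_records, nrow, integer(1)) > 0)[1]
  expect_equal(back$fv_records[[i]]$food_code, d$fv_records[[i]]$food_code)
  expect_equal(back$fv_records[[i]]$quantity, d$fv_records[[i]]$quantity)

  m <- true_model(beta_lead = 0.2)
  fy <- tempfile(fileext = ".yaml")
  write_true_model_yaml(m, fy)
  m2 <- read_true_model_yaml(fy)
  expect_equal(m2$beta_lead, 0.2)
  expect_equal(m2$causes$cvd$intercept, m$causes$cvd$intercept)
  expect_equal(unname(unlist(m2$beta_ix)), unname(unlist(m$beta_ix)))
})
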