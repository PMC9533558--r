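# The pooled logistic g-formula estimator.

# one moderate prepared cohort shared across estimator tests
gf_cohort <- function() {
  if (is.null(.fixture_env$gf_prep)) {
    ch <- cached_cohort("gf_default", 3000, seed = 17)
    .fixture_env$gf_prep <- prepare_cohort(ch)$cohort
  }
  .fixture_env$gf_prep
}

test_that("cumulative risk follows the discrete-time identity", {
  expect_equal(cumulative_risk(rep(0.1, 3)), 1 - 0.9^3)
  expect_equal(cumulative_risk(c(0.2, 1, 0.1)), 1)
  expect_equal(cumulative_risk(rep(0, 10)), 0)
  expect_error(cumulative_risk(c(0.5, 1.2)), "0, 1")
  # monotone in each hazard and in the horizon
  h <- c(0.05, 0.1, 0.2)
  expect_gt(cumulative_risk(c(h, 0.01)), cumulative_risk(h))
  h2 <- h; h2[2] <- 0.3
  expect_gt(cumulative_risk(h2), cumulative_risk(h))
})

test_that("contrasts obey their algebra", {
  ct <- contrast(0.02, 0.04)
  expect_equal(ct$rr, 0.5)
  expect_equal(ct$rd_pts, -2)
  expect_equal(contrast(0.3, 0.3), list(rr = 1, rd_pts = 0))
  # ref*RR and ref + RD/100 reconstruct the intervened risk identically
  for (pair in list(c(0.0588, 0.0342), c(0.41, 0.12), c(0.007, 0.31))) {
    ct <- contrast(pair[1], pair[2])
    expect_equal(pair[2] * ct$rr, pair[1], tolerance = 1e-12)
    expect_equal(pair[2] + ct$rd_pts / 100, pair[1], tolerance = 1e-12)
  }
  expect_warning(ct0 <- contrast(0.1, 0), "undefined")
  expect_true(is.na(ct0$rr))
  expect_equal(ct0$rd_pts, 10)
})

test_that("fitting is reproducible and invariant to weight splitting", {
  d <- gf_cohort()
  pt <- expand_person_time(d, prep_config(), "all")
  spec <- hazard_model_spec(cause = "all", diet = "dii")
  f1 <- fit_pooled_logistic(pt, spec)
  f2 <- fit_pooled_logistic(pt, spec)
  expect_lt(max(abs(f1$coefficients - f2$coefficients)), 1e-8)
  # duplicate every row at half weight: same likelihood, same estimate
  pt2 <- rbind(pt, pt)
  pt2$survey_weight <- pt2$survey_weight / 2
  f3 <- fit_pooled_logistic(pt2, spec)
  expect_equal(f3$coefficients, f1$coefficients, tolerance = 1e-7)
  expect_true(all(is.finite(f1$coefficients)))
})

test_that("rank-deficient designs are rejected with the collinear term named", {
  d <- gf_cohort()
  d$lead_copy <- d$lead_log2
  pt <- expand_person_time(d, prep_config(), "all")
  spec <- hazard_model_spec(cause = "all", diet = "dii",
                            covariate_terms = c("age", "sex", "lead_copy"))
  expect_error(fit_pooled_logistic(pt, spec), "collinear")
})

test_that("the identity intervention reproduces the natural course exactly", {
  d <- gf_cohort()
  pt <- expand_person_time(d, prep_config(), "all")
  fit <- fit_pooled_logistic(pt, hazard_model_spec(cause = "all", diet = "dii"))
  r1 <- estimate_scenario_risk(fit, d, intervention("natural_course"))
  r2 <- estimate_scenario_risk(fit, d, intervention("nc2"))
  expect_identical(as.numeric(r1), as.numeric(r2))
  ct <- contrast(as.numeric(r1), as.numeric(r2))
  expect_identical(ct$rr, 1)
  expect_identical(ct$rd_pts, 0)
})

test_that("scenario risks match a direct closed-form recomputation", {
  d <- gf_cohort()
  pt <- expand_person_time(d, prep_config(), "cvd")
  spec <- hazard_model_spec(cause = "cvd", diet = "dii")
  fit <- fit_pooled_logistic(pt, spec)
  iv <- intervention("cap_lead", rule("blood_lead", "cap", percentile = 25))
  sub <- d[1:250, ]
  est <- as.numeric(estimate_scenario_risk(fit, sub, iv))
  # independent recomputation: modify the data by hand, build one long
  # person-by-interval design, and multiply the survival terms directly
  d2 <- sub
  cut <- weighted_percentile(d2$blood_lead, d2$survey_weight, 25)
  d2$blood_lead <- pmin(d2$blood_lead, cut)
  d2$lead_log2 <- log2(d2$blood_lead)
  long <- d2[rep(seq_len(nrow(d2)), each = 27), ]
  long$t <- rep(1:27, nrow(d2))
  long$event <- 0
  X <- envgform:::build_design(long, spec, xlev = fit$xlevels)$X
  h <- matrix(plogis(drop(X %*% fit$coefficients)), ncol = 27, byrow = TRUE)
  risks <- 1 - apply(1 - h, 1, prod)
  manual <- weighted.mean(risks, d2$survey_weight)
  expect_equal(est, manual, tolerance = 1e-10)
})

test_that("capping a harmful metal never raises the estimated risk", {
  d <- gf_cohort()
  pt <- expand_person_time(d, prep_config(), "all")
  fit <- fit_pooled_logistic(pt, hazard_model_spec(cause = "all", diet = "dii"))
  risks <- vapply(c(100, 75, 50, 25, 5), function(p)
    as.numeric(estimate_scenario_risk(
      fit, d, intervention("cap", rule("blood_lead", "cap", percentile = p)))),
    numeric(1))
  expect_true(all(diff(risks) <= 1e-12))
})

test_that("bootstrap is deterministic, honest about failures, and collapses
          for a constant statistic", {
  d <- gf_cohort()[1:200, ]
  stat_mean <- function(ch, idx) c(m = weighted.mean(ch$age, ch$survey_weight))
  b1 <- bootstrap_ci(stat_mean, d, M = 50, seed = 5)
  b2 <- bootstrap_ci(stat_mean, d, M = 50, seed = 5)
  expect_identical(b1$lower, b2$lower)
  expect_identical(b1$upper, b2$upper)
  b3 <- bootstrap_ci(stat_mean, d, M = 50, seed = 6)
  expect_false(identical(b1$lower, b3$lower))
  # constant statistic -> degenerate interval at the point value
  bconst <- bootstrap_ci(function(ch, idx) c(k = 42), d, M = 20, seed = 1)
  expect_equal(unname(bconst$lower), 42)
  expect_equal(unname(bconst$upper), 42)
  # > 10% failures is an error
  stat_flaky <- function(ch, idx) {
    if (idx[1] %% 3 == 0) stop("unlucky replicate")
    c(m = mean(ch$age))
  }
  expect_error(bootstrap_ci(stat_flaky, d, M = 30, seed = 2), "10%")
})

test_that("bootstrap CI width shrinks as the cohort grows", {
  spec <- hazard_model_spec(cause = "all", diet = "dii",
                            covariate_terms = c("age", "sex", "smoking"))
  scen <- default_scenarios("dii")[c("natural_course", "lower_both_metals")]
  widths <- vapply(c(1000, 4000), function(n) {
    ch <- prepare_cohort(generate_cohort(cohort_config(n, seed = 33)))$cohort
    res <- run_gformula(ch, scen, spec, causes = "all", M = 40, seed = 2)
    row <- res[res$scenario == "lower_both_metals" &
                 res$reference == "natural_course", ]
    row$rr_hi - row$rr_lo
  }, numeric(1))
  expect_lt(widths[2], widths[1])
})

test_that("run_gformula emits the cause x scenario x reference grid", {
  d <- gf_cohort()
  scen <- default_scenarios("dii")[c("natural_course", "lower_both_metals",
                                     "worst_case")]
  res <- run_gformula(d, scen, hazard_model_spec(diet = "dii"),
                      causes = c("all", "cvd"), M = 0, seed = 1)
  expect_equal(nrow(res), 2 * 3 * 2)  # causes x scenarios x references
  nc <- res[res$scenario == "natural_course" &
              res$reference == "natural_course", ]
  expect_true(all(nc$rr == 1))
  expect_true(all(nc$rd_pts == 0))
  wc <- res[res$scenario == "worst_case" & res$reference == "worst_case", ]
  expect_true(all(wc$rr == 1))
  expect_true(all(res$risk >= 0 & res$risk <= 1))
  # single-scenario run: one row per reference, RR 1 vs itself
  res1 <- run_gformula(d, list(intervention("natural_course")),
                       hazard_model_spec(diet = "dii"),
                       causes = "all", M = 0, seed = 1)
  expect_equal(nrow(res1), 1L)
  expect_equal(res1$rr, 1)
  expect_equal(res1$rd_pts, 0)
})
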