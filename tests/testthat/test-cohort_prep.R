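# Deterministic preprocessing: exclusions, LOD imputation, creatinine
# correction, person-time expansion, weighted percentiles, geometric stats.

test_that("below-LOD imputation returns LOD/sqrt(2) and passes others through", {
  expect_equal(impute_below_lod(0.3, TRUE, 1.0), 1 / sqrt(2))
  expect_equal(round(impute_below_lod(0.3, TRUE, 1.0), 1), 0.7)
  expect_equal(impute_below_lod(2.5, FALSE, 1.0), 2.5)
  expect_equal(impute_below_lod(0.01, TRUE, 0.03), 0.03 / sqrt(2))
  # never increases an above-LOD value, output always positive
  x <- c(0.2, 0.9, 1.0, 5.3)
  flag <- x < 1
  out <- impute_below_lod(x, flag, 1.0)
  expect_true(all(out[!flag] == x[!flag]))
  expect_true(all(out > 0))
  expect_error(impute_below_lod(-1, FALSE, 1.0), "negative")
})

test_that("creatinine correction divides and validates", {
  expect_equal(creatinine_correct(0.5, 1.25), 0.4)
  expect_equal(creatinine_correct(0, 2), 0)
  expect_equal(creatinine_correct(0.36, 1.0), 0.36)
  expect_error(creatinine_correct(0.5, 0, id = "P1"), "P1")
})

test_that("log2 transform obeys the doubling property and rejects x <= 0", {
  expect_equal(log2_exposure(4), 2)
  expect_equal(log2_exposure(1), 0)
  for (x in c(0.7, 2.97, 10))
    expect_equal(log2_exposure(2 * x) - log2_exposure(x), 1)
  expect_error(log2_exposure(0), "positive")
})

test_that("exclusions drop incomplete rows, log reasons, and are idempotent", {
  d <- tiny_cohort()
  res <- apply_exclusions(d)
  expect_identical(res$cohort, d)
  expect_equal(sum(res$log$n_excluded), 0L)

  d2 <- d
  d2$bmi[2] <- NA
  d2$died[3] <- NA
  res2 <- apply_exclusions(d2)
  expect_equal(nrow(res2$cohort), nrow(d) - 2L)
  expect_equal(res2$log$n_excluded[res2$log$reason == "bmi"], 1L)
  expect_equal(res2$log$n_excluded[res2$log$reason == "died"], 1L)
  # idempotent
  res3 <- apply_exclusions(res2$cohort)
  expect_identical(res3$cohort, res2$cohort)

  # all rows missing one covariate -> all attributed to it
  d4 <- d
  d4$smoking <- NA_character_
  expect_warning(res4 <- apply_exclusions(d4), "all participants")
  expect_equal(nrow(res4$cohort), 0L)
  expect_equal(res4$log$n_excluded[res4$log$reason == "smoking"], nrow(d))
})

test_that("person-time expansion follows the final-interval event convention", {
  d <- tiny_cohort()
  cfg <- prep_config()
  pt <- expand_person_time(d, cfg, "cvd")
  # participant 1: follow-up 3.4y, died of cvd -> 4 rows, event 0001
  p1 <- pt[pt$id == "T01", ]
  expect_equal(nrow(p1), 4L)
  expect_equal(p1$event, c(0, 0, 0, 1))
  expect_equal(p1$t, 1:4)
  # participant 3 died of cancer -> censored for cvd
  p3 <- pt[pt$id == "T03", ]
  expect_equal(sum(p3$event), 0)
  expect_equal(nrow(p3), 10L)
  # survivor with 27y follow-up -> horizon rows, all 0
  p2 <- pt[pt$id == "T02", ]
  expect_equal(nrow(p2), 27L)
  expect_equal(sum(p2$event), 0)
  # all-cause: one event per death within horizon; total rows match
  pt_all <- expand_person_time(d, cfg, "all")
  expect_equal(sum(pt_all$event), sum(d$died))
  expect_equal(nrow(pt_all),
               sum(pmin(ceiling(d$followup_years), cfg$horizon_years)))
  expect_error(expand_person_time(transform(d, followup_years = 0), cfg),
               "non-positive")
})

test_that("weighted percentile matches hand computations and boundary rules", {
  expect_equal(weighted_percentile(1:4, rep(1, 4), 50), 2.5)
  expect_equal(weighted_percentile(c(3, 1, 9), rep(1, 3), 0), 1)
  expect_equal(weighted_percentile(c(3, 1, 9), rep(1, 3), 100), 9)
  # point mass: all weight on a single value
  for (p in c(0, 12, 50, 88, 100)) {
    expect_equal(weighted_percentile(5, 2, p), 5)
    expect_equal(weighted_percentile(rep(5, 4), c(1, 2, 3, 4), p), 5)
  }
  expect_error(weighted_percentile(numeric(0), numeric(0), 50), "empty")
})

test_that("weighted percentile is monotone in p and affine-equivariant", {
  set.seed(42)
  for (rep in 1:5) {
    x <- rlnorm(23)
    w <- rgamma(23, 2)
    p <- sort(runif(7, 0, 100))
    q <- weighted_percentile(x, w, p)
    expect_true(all(diff(q) >= -1e-12))
    a <- runif(1, 0.5, 3); b <- runif(1, -2, 2)
    expect_equal(weighted_percentile(a * x + b, w, p), a * q + b,
                 tolerance = 1e-10)
  }
})

test_that("geometric statistics match closed forms", {
  gs <- compute_geometric_stats(c(2, 8))
  expect_equal(gs$gm, 4)
  gs2 <- compute_geometric_stats(rep(3.7, 5))
  expect_equal(gs2$gm, 3.7)
  expect_equal(gs2$gse, 1)
  expect_equal(gs2$gm_se, 0)
  expect_equal(compute_geometric_stats(c(1, 10, 100))$gm, 10)
  expect_error(compute_geometric_stats(c(1, 0)), "positive")
})

test_that("prepare_cohort imputes, corrects, and appends transforms", {
  d <- tiny_cohort()
  out <- prepare_cohort(d)$cohort
  expect_equal(out$blood_lead[1], 1 / sqrt(2))  # was 0.5, below LOD
  expect_equal(out$blood_lead[-1], d$blood_lead[-1])
  expect_equal(out$ucd_creat, d$urinary_cadmium / d$urinary_creatinine)
  expect_equal(out$lead_log2, log2(out$blood_lead))
  expect_equal(out$ucd_creat_log2, log2(out$ucd_creat))
})
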