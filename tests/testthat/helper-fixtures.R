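# Shared fixtures, built in code.

# A tiny hand-written cohort with every column the pipeline needs; values
# chosen so derived quantities are easy to verify by hand.
tiny_cohort <- function(n = 6) {
  set.seed(123)
  d <- data.frame(
    id = sprintf("T%02d", seq_len(n)),
    age = seq(30, 80, length.out = n),
    sex = rep(c("male", "female"), length.out = n),
    ethnicity = rep(c("not_hispanic", "mexican_american", "other_hispanic"),
                    length.out = n),
    poverty_income_tertile = rep(1:3, length.out = n),
    education_years = rep(c(9, 12, 16), length.out = n),
    residence = rep(c("metro", "nonmetro"), length.out = n),
    smoking = rep(c("never", "current", "former"), length.out = n),
    bmi = seq(20, 35, length.out = n),
    physical_activity = rep(c("none", "1_14", "15_plus"), length.out = n),
    blood_lead = c(0.5, 2, 4, 8, 3, 6)[seq_len(n)],
    urinary_cadmium = c(0.1, 0.4, 0.8, 1.2, 0.5, 0.3)[seq_len(n)],
    urinary_creatinine = c(0.5, 1, 2, 1.5, 1, 0.6)[seq_len(n)],
    survey_weight = c(1, 2, 1, 0.5, 1.5, 1)[seq_len(n)],
    followup_years = c(3.4, 27, 10, 27, 5, 27)[seq_len(n)],
    died = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)[seq_len(n)],
    cause = c("cvd", "none", "cancer", "none", "other", "none")[seq_len(n)],
    stringsAsFactors = FALSE
  )
  d$lead_below_lod <- d$blood_lead < 1
  d
}

# A small diet table for DII arithmetic, using a 3-component registry.
toy_registry <- function() {
  dii_registry(c("fiber", "saturated_fat", "vitamin_c"),
               weights = c(0.5, -0.2, 0.1),
               energy_adjust = c(TRUE, TRUE, FALSE))
}

toy_diet <- function() {
  data.frame(id = c("A", "B"),
             diet_energy_kcal = c(2000, 1000),
             diet_fiber = c(60, 10),
             diet_saturated_fat = c(30, 20),
             diet_vitamin_c = c(90, 30))
}

# Small generated cohorts, memoized across test files for speed.
.fixture_env <- new.env(parent = emptyenv())
cached_cohort <- function(key, n, seed, model = true_model(), ...) {
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_cohort(
      cohort_config(n, seed, ...), model)
  }
  .fixture_env[[key]]
}
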