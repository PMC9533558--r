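# Deterministic cohort preprocessing: exclusions, below-LOD imputation,
# creatinine correction, log2 transforms, person-time expansion, weighted
# percentiles and descriptive geometric statistics.

#' Preprocessing configuration
#'
#' Holds the laboratory detection limits and the discrete-time grid used
#' throughout the pipeline. The defaults are the assay detection limits for
#' blood lead (1.0 ug/dL) and urinary cadmium (0.03 ug/L) and a 27-year
#' horizon on annual intervals.
#'
#' @param lod_lead blood lead detection limit, ug/dL
#' @param lod_cadmium urinary cadmium detection limit, ug/L
#' @param horizon_years administrative horizon of the risk estimate, years
#' @param interval_years width of a discrete-time interval (currently 1)
#' @return an object of class `prep_config`
#' @export
#' @examples
#' prep_config()
prep_config <- function(lod_lead = 1.0, lod_cadmium = 0.03,
                        horizon_years = 27L, interval_years = 1L) {
  stopifnot(lod_lead > 0, lod_cadmium > 0,
            horizon_years >= 1, interval_years == 1L)
  structure(list(lod_lead = lod_lead, lod_cadmium = lod_cadmium,
                 horizon_years = as.integer(horizon_years),
                 interval_years = 1L),
            class = "prep_config")
}

# Columns that must be complete for a participant to enter the analysis:
# vital status / follow-up plus the full adjustment set.
mortality_columns <- function() c("followup_years", "died", "cause")
adjustment_columns <- function() {
  c("age", "sex", "ethnicity", "poverty_income_tertile", "education_years",
    "residence", "smoking", "bmi", "physical_activity")
}

#' Apply complete-case exclusions
#'
#' Removes participants with missing vital-status/follow-up data or any
#' missing adjustment covariate, and returns an exclusion log attributing
#' removals to the first missing column found (columns checked in a fixed
#' order, mortality first). Idempotent: running it twice removes nothing
#' on the second pass.
#'
#' @param cohort a cohort data frame (one row per participant)
#' @param columns character vector of columns required to be non-missing;
#'   defaults to the mortality columns plus the adjustment set
#' @return a list with elements `cohort` (retained rows), and `log`, a data
#'   frame with one row per checked column (`reason`, `n_excluded`) plus
#'   attributes `n_input`, `n_retained`
#' @export
apply_exclusions <- function(cohort,
                             columns = c(mortality_columns(), adjustment_columns())) {
  stopifnot(is.data.frame(cohort))
  columns <- intersect(columns, names(cohort))
  n_in <- nrow(cohort)
  attributed <- rep(NA_character_, n_in)
  for (col in columns) {
    miss <- is.na(cohort[[col]]) & is.na(attributed)
    attributed[miss] <- col
  }
  keep <- is.na(attributed)
  log <- data.frame(reason = columns,
                    n_excluded = vapply(columns, function(col)
                      sum(attributed == col, na.rm = TRUE), integer(1)),
                    row.names = NULL)
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("all participants excluded")
  attr(log, "n_input") <- n_in
  attr(log, "n_retained") <- nrow(out)
  list(cohort = out, log = log)
}

#' Impute concentrations below the limit of detection
#'
#' Measurements flagged below the LOD are replaced by LOD/sqrt(2), the
#' standard single-value imputation for left-censored assay data; values at
#' or above the LOD pass through unchanged.
#'
#' @param value numeric concentrations
#' @param below_lod logical flags, same length
#' @param lod the detection limit (positive scalar)
#' @return numeric vector with flagged entries set to `lod / sqrt(2)`
#' @export
#' @examples
#' impute_below_lod(c(0.3, 2.5), c(TRUE, FALSE), lod = 1.0)
impute_below_lod <- function(value, below_lod, lod) {
  stopifnot(length(lod) == 1L, lod > 0, length(value) == length(below_lod),
            is.logical(below_lod), !anyNA(below_lod))
  if (any(value < 0 & !below_lod))
    stop("negative concentration not flagged below LOD")
  ifelse(below_lod, lod / sqrt(2), value)
}

#' Creatinine-correct urinary cadmium
#'
#' Expresses urinary cadmium per gram of creatinine (ug/g) to account for
#' between-participant differences in urine dilution.
#'
#' @param ucd urinary cadmium, ug/L
#' @param creatinine urinary creatinine, g/L (must be positive)
#' @param id optional participant ids used in error messages
#' @return ucd / creatinine, in ug/g
#' @export
creatinine_correct <- function(ucd, creatinine, id = NULL) {
  stopifnot(length(ucd) == length(creatinine))
  bad <- which(!(creatinine > 0))
  if (length(bad)) {
    who <- if (!is.null(id)) paste(id[bad], collapse = ", ")
           else paste(bad, collapse = ", ")
    stop("non-positive creatinine for participant(s): ", who)
  }
  ucd / creatinine
}

#' Base-2 logarithm of a positive exposure
#'
#' Exposures are modelled per doubling, so concentrations enter the hazard
#' model on the log2 scale; a doubling increases the transformed value by
#' exactly 1.
#'
#' @param x positive numeric vector
#' @return log2(x)
#' @export
log2_exposure <- function(x) {
  if (any(!(x > 0))) stop("log2 transform requires strictly positive values")
  log2(x)
}

#' Run the full deterministic preparation of a raw cohort
#'
#' Applies complete-case exclusions, imputes below-LOD lead (and, when a
#' `cadmium_below_lod` flag is present, cadmium), creatinine-corrects
#' urinary cadmium, and appends the log2-transformed exposure columns
#' (`lead_log2`, `ucd_creat`, `ucd_creat_log2`). Existing columns are never
#' overwritten except `blood_lead`, which is replaced by its LOD-imputed
#' version.
#'
#' @param cohort raw cohort data frame
#' @param config a [prep_config()]
#' @return a list with `cohort` (prepared) and `exclusion_log`
#' @export
prepare_cohort <- function(cohort, config = prep_config()) {
  stopifnot(inherits(config, "prep_config"))
  ex <- apply_exclusions(cohort)
  d <- ex$cohort
  if (nrow(d) == 0L) return(list(cohort = d, exclusion_log = ex$log))
  d$blood_lead <- impute_below_lod(d$blood_lead, d$lead_below_lod,
                                   config$lod_lead)
  if (!is.null(d$cadmium_below_lod)) {
    d$urinary_cadmium <- impute_below_lod(d$urinary_cadmium,
                                          d$cadmium_below_lod,
                                          config$lod_cadmium)
  }
  d$ucd_creat <- creatinine_correct(d$urinary_cadmium, d$urinary_creatinine,
                                    id = d$id)
  d$lead_log2 <- log2_exposure(d$blood_lead)
  d$ucd_creat_log2 <- log2_exposure(d$ucd_creat)
  list(cohort = d, exclusion_log = ex$log)
}

#' Expand a cohort into a person-time table
#'
#' One row per participant per discrete annual interval at risk, up to
#' `min(ceiling(followup_years), horizon)`. The event indicator is 1 only in
#' a participant's final interval and only if they died of the selected
#' cause within the horizon; deaths from competing causes are censored at
#' their final interval (cause-specific censoring), and survivors carry 0
#' throughout.
#'
#' @param cohort prepared cohort data frame
#' @param config a [prep_config()]
#' @param cause `"all"`, `"cvd"`, `"cancer"` or `"other"`
#' @return a data frame with all cohort columns plus `t` (1-based interval
#'   index) and `event`
#' @export
expand_person_time <- function(cohort, config = prep_config(),
                               cause = c("all", "cvd", "cancer", "other")) {
  cause <- match.arg(cause)
  stopifnot(inherits(config, "prep_config"))
  if (any(!(cohort$followup_years > 0))) stop("non-positive follow-up time")
  horizon <- config$horizon_years
  n_int <- pmin(as.integer(ceiling(cohort$followup_years)), horizon)
  idx <- rep.int(seq_len(nrow(cohort)), n_int)
  pt <- cohort[idx, , drop = FALSE]
  rownames(pt) <- NULL
  pt$t <- sequence(n_int)
  is_case <- cohort$died & (cohort$cause == cause | cause == "all") &
    ceiling(cohort$followup_years) <= horizon
  last_row <- cumsum(n_int)
  ev <- numeric(nrow(pt))
  ev[last_row[is_case]] <- 1
  pt$event <- ev
  pt
}

#' Weighted percentile of an empirical distribution
#'
#' Inverts the weighted ECDF with linear interpolation between adjacent
#' order statistics at cumulative-weight midpoints. With equal weights this
#' reduces to a standard continuous sample quantile; it is monotone
#' non-decreasing in `p` and equivariant under increasing affine maps.
#'
#' @param values numeric vector (at least one value)
#' @param weights positive weights, same length
#' @param p percentile(s) in [0, 100]
#' @return numeric vector, one entry per `p`
#' @export
#' @examples
#' weighted_percentile(1:4, rep(1, 4), 50)  # 2.5
weighted_percentile <- function(values, weights = rep(1, length(values)), p) {
  if (length(values) == 0L) stop("empty input")
  stopifnot(length(values) == length(weights), all(weights > 0),
            all(p >= 0), all(p <= 100))
  o <- order(values)
  v <- values[o]
  w <- weights[o] / sum(weights)
  midpoints <- cumsum(w) - w / 2
  vapply(p / 100, function(q) {
    if (q <= midpoints[1L]) return(v[1L])
    if (q >= midpoints[length(midpoints)]) return(v[length(v)])
    stats::approx(midpoints, v, xout = q, ties = "ordered")$y
  }, numeric(1))
}

#' Weighted geometric mean and geometric standard error
#'
#' GM = exp(weighted mean of ln x); the GSE is exp of the standard error of
#' that weighted mean, computed with normalized weights as
#' sqrt(sum(u_i^2 (ln x_i - m)^2)). A constant sequence has GM equal to the
#' constant and GSE exactly 1.
#'
#' @param values positive numeric vector
#' @param weights positive weights
#' @return named list with `gm`, `gse`, and `gm_se`, the delta-method
#'   standard error of the GM itself (`gm` times the log-scale SE), the
#'   form usually printed next to geometric means in descriptive tables
#' @export
compute_geometric_stats <- function(values, weights = rep(1, length(values))) {
  if (any(!(values > 0))) stop("geometric statistics require positive values")
  stopifnot(length(values) == length(weights), all(weights > 0))
  u <- weights / sum(weights)
  l <- log(values)
  m <- sum(u * l)
  se <- sqrt(sum(u^2 * (l - m)^2))
  list(gm = exp(m), gse = exp(se), gm_se = exp(m) * se)
}
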