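# Plain-text round trips: cohort tables as CSV (fruit/vegetable records
# JSON-encoded in one column), true models / cohort configs / scenario
# sets as YAML.

#' Write / read a cohort table as CSV
#'
#' The `fv_records` list column is serialized as a JSON-encoded string
#' column; every other column is plain CSV. Reading restores the list
#' column and column types.
#'
#' @param cohort cohort data frame
#' @param path CSV file path
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the cohort data frame
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- cohort
  if (!is.null(out$fv_records)) {
    out$fv_records <- vapply(out$fv_records, function(r)
      as.character(jsonlite::toJSON(r, dataframe = "rows")), character(1))
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(d$fv_records)) {
    d$fv_records <- lapply(d$fv_records, function(s) {
      r <- jsonlite::fromJSON(s)
      if (NROW(r) == 0L)
        data.frame(food_code = character(0), quantity = numeric(0))
      else r
    })
  }
  d
}

#' Write / read a true model as YAML
#'
#' @param model a [true_model()]
#' @param path YAML file path
#' @return the path (write) or a reconstructed `true_model` (read)
#' @export
write_true_model_yaml <- function(model, path) {
  stopifnot(inherits(model, "true_model"))
  yaml::write_yaml(list(
    causes = model$causes,
    beta_lead = model$beta_lead, beta_cadmium = model$beta_cadmium,
    beta_dii = model$beta_dii, beta_fv = model$beta_fv,
    beta_ix = as.list(model$beta_ix),
    covariate_effects = as.list(model$covariate_effects),
    exposure_distribution = rapply(model$exposure_distribution, as.list,
                                   how = "replace"),
    lod_lead = model$lod_lead,
    max_followup_years = model$max_followup_years), path)
  invisible(path)
}

#' @rdname write_true_model_yaml
#' @export
read_true_model_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  true_model(
    causes = cfg$causes,
    beta_lead = cfg$beta_lead, beta_cadmium = cfg$beta_cadmium,
    beta_dii = cfg$beta_dii, beta_fv = cfg$beta_fv,
    beta_ix = unlist(cfg$beta_ix),
    covariate_effects = unlist(cfg$covariate_effects),
    exposure_distribution = lapply(cfg$exposure_distribution, function(e)
      lapply(e, function(v) if (is.list(v)) unlist(v) else v)),
    lod_lead = cfg$lod_lead,
    max_followup_years = cfg$max_followup_years)
}

#' Read a scenario set from YAML
#'
#' The file holds a `scenarios` list; each scenario has a `name` and a
#' list of `rules` with fields `variable`, `mode` and either `percentile`
#' or `value`.
#'
#' @param path YAML file path
#' @return named list of [intervention()]s
#' @export
read_scenarios_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(cfg$scenarios, function(sc) {
    rules <- lapply(sc$rules %||% list(), function(r)
      rule(r$variable, r$mode, percentile = r$percentile, value = r$value))
    intervention(sc$name, rules)
  })
  stats::setNames(out, vapply(out, `[[`, character(1), "name"))
}

#' Write g-formula results as CSV and JSON
#'
#' @param results the data frame returned by [run_gformula()]
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "results.csv")
  js <- file.path(dir, "results.json")
  utils::write.csv(results, csv, row.names = FALSE)
  jsonlite::write_json(results, js, dataframe = "rows", digits = NA,
                       na = "null")
  invisible(c(csv = csv, json = js))
}
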