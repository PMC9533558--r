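# Hypothetical interventions: ordered cap/floor/set rules on exposure
# columns, with targets given either as weighted percentiles of the
# observed (pre-intervention) distribution or as absolute values.

INTERVENABLE <- c("blood_lead", "ucd_creat", "dii", "fv_servings")

#' Define a single intervention rule
#'
#' `cap` lowers values above the target to the target ("lower to"),
#' `floor` raises values below it ("increase to"), and `set` assigns the
#' target to everyone. Exactly one of `percentile` (of the weighted
#' observed distribution) or `value` must be given.
#'
#' @param variable one of `blood_lead`, `ucd_creat`, `dii`, `fv_servings`
#' @param mode `"cap"`, `"floor"` or `"set"`
#' @param percentile target percentile in [0, 100], or NULL
#' @param value absolute target, or NULL
#' @return a list of class `intervention_rule`
#' @export
rule <- function(variable, mode = c("cap", "floor", "set"),
                 percentile = NULL, value = NULL) {
  mode <- match.arg(mode)
  if (!variable %in% INTERVENABLE)
    stop("cannot intervene on variable: ", variable)
  if (is.null(percentile) == is.null(value))
    stop("give exactly one of percentile or value")
  if (!is.null(percentile))
    stopifnot(percentile >= 0, percentile <= 100)
  structure(list(variable = variable, mode = mode,
                 percentile = percentile, value = value),
            class = "intervention_rule")
}

#' Define a hypothetical intervention
#'
#' An ordered list of [rule()]s applied jointly from the start of
#' follow-up. An intervention with no rules is the natural course
#' (no intervention).
#'
#' @param name scenario label used in reports
#' @param ... zero or more [rule()]s
#' @return a list of class `intervention`
#' @export
#' @examples
#' intervention("lower_lead_p5", rule("blood_lead", "cap", percentile = 5))
intervention <- function(name, ...) {
  rules <- list(...)
  if (length(rules) == 1L && is.list(rules[[1L]]) &&
      !inherits(rules[[1L]], "intervention_rule")) rules <- rules[[1L]]
  stopifnot(all(vapply(rules, inherits, logical(1), "intervention_rule")))
  structure(list(name = name, rules = rules), class = "intervention")
}

#' Apply an intervention to a cohort
#'
#' Percentile targets are resolved on the weighted PRE-intervention
#' distribution of each variable (all targets are computed before any rule
#' modifies the data); rules are then applied in order. Returns a modified
#' copy; the input is never mutated. The resolved cutoffs are attached as
#' the `"targets"` attribute for logging.
#'
#' @param cohort cohort data frame containing the intervened columns
#' @param iv an [intervention()]
#' @param weights survey weights used to resolve percentile targets;
#'   defaults to the cohort's `survey_weight` column
#' @return the modified cohort
#' @export
apply_intervention <- function(cohort, iv,
                               weights = cohort$survey_weight) {
  stopifnot(inherits(iv, "intervention"))
  if (length(iv$rules) == 0L) {
    attr(cohort, "targets") <- numeric(0)
    return(cohort)
  }
  for (r in iv$rules) {
    if (is.null(cohort[[r$variable]]))
      stop("cohort lacks intervened column: ", r$variable)
  }
  targets <- vapply(iv$rules, function(r) {
    if (!is.null(r$value)) r$value
    else weighted_percentile(cohort[[r$variable]], weights, r$percentile)
  }, numeric(1))
  names(targets) <- vapply(iv$rules, function(r)
    paste0(r$variable, ":", r$mode), character(1))
  for (k in seq_along(iv$rules)) {
    r <- iv$rules[[k]]
    x <- cohort[[r$variable]]
    cohort[[r$variable]] <- switch(r$mode,
      cap = pmin(x, targets[k]),
      floor = pmax(x, targets[k]),
      set = rep(targets[k], length(x)))
  }
  attr(cohort, "targets") <- targets
  cohort
}

#' The six default intervention scenarios
#'
#' The shipped scenario set: lower each metal to a low percentile (default
#' 5th) separately and jointly; improve the diet (raise the inflammatory
#' index to its 75th percentile, or raise fruit-and-vegetable servings to
#' 5/day); a best case combining both; and a worst case raising both metals
#' to a high percentile (default 95th) while worsening the diet. Percentile
#' defaults follow the headline tables; pass `metal_low = 25`,
#' `metal_high = 75` for the alternative parameterization.
#'
#' @param diet `"dii"` or `"fv_servings"`
#' @param metal_low,metal_high percentiles for the lowered / raised metals
#' @param diet_high,diet_low percentiles for the improved / worsened DII
#' @param fv_target servings/day floor for the improved FV scenario
#' @param fv_low servings/day cap for the worst-case FV scenario
#' @return named list of [intervention()]s including `natural_course` and
#'   `worst_case`
#' @export
default_scenarios <- function(diet = c("dii", "fv_servings"),
                              metal_low = 5, metal_high = 95,
                              diet_high = 75, diet_low = 25,
                              fv_target = 5, fv_low = 2) {
  diet <- match.arg(diet)
  diet_up <- if (diet == "dii")
    rule("dii", "floor", percentile = diet_high)
  else rule("fv_servings", "floor", value = fv_target)
  diet_down <- if (diet == "dii")
    rule("dii", "cap", percentile = diet_low)
  else rule("fv_servings", "cap", value = fv_low)
  list(
    natural_course = intervention("natural_course"),
    lower_lead = intervention("lower_lead",
      rule("blood_lead", "cap", percentile = metal_low)),
    lower_cadmium = intervention("lower_cadmium",
      rule("ucd_creat", "cap", percentile = metal_low)),
    lower_both_metals = intervention("lower_both_metals",
      rule("blood_lead", "cap", percentile = metal_low),
      rule("ucd_creat", "cap", percentile = metal_low)),
    improve_diet = intervention("improve_diet", diet_up),
    best_case = intervention("best_case",
      rule("blood_lead", "cap", percentile = metal_low),
      rule("ucd_creat", "cap", percentile = metal_low),
      diet_up),
    worst_case = intervention("worst_case",
      rule("blood_lead", "floor", percentile = metal_high),
      rule("ucd_creat", "floor", percentile = metal_high),
      diet_down)
  )
}
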