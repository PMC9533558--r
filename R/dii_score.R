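# Adapted dietary inflammatory index (DII) and daily fruit-and-vegetable
# servings, computed from single-recall dietary data.
#
# The DII here is a weighted sum of standardized, energy-adjusted component
# intakes over 24 nutrients/food constituents. Under the default ("paper")
# sign convention a POSITIVE score indicates an anti-inflammatory diet;
# the "classic" convention (positive = pro-inflammatory) negates every
# score exactly.

# The 24 components of the adapted index, in canonical order.
DII_COMPONENTS <- c(
  "carbohydrate", "protein", "alcohol", "fiber", "cholesterol",
  "saturated_fat", "monounsaturated_fat", "omega3", "omega6",
  "niacin", "thiamin", "riboflavin", "vitamin_b6", "vitamin_b12",
  "iron", "magnesium", "zinc", "vitamin_a", "vitamin_c", "vitamin_d",
  "vitamin_e", "folic_acid", "beta_carotene", "caffeine"
)

#' Construct a DII weight registry
#'
#' A registry lists the index components with their signed inflammatory
#' weights and whether each is expressed per 1000 kcal before
#' standardization. Weights are oriented so that a positive weight means
#' the component contributes anti-inflammatory potential under the default
#' sign convention.
#'
#' @param components character vector of component names (unique)
#' @param weights signed numeric weights, same length
#' @param energy_adjust logical flags, same length (recycled if scalar)
#' @return a data frame of class `dii_registry`
#' @export
dii_registry <- function(components, weights, energy_adjust = TRUE) {
  stopifnot(length(components) == length(weights),
            !anyDuplicated(components), all(is.finite(weights)))
  energy_adjust <- rep_len(as.logical(energy_adjust), length(components))
  structure(data.frame(component = as.character(components),
                       weight = as.numeric(weights),
                       energy_adjust = energy_adjust,
                       stringsAsFactors = FALSE),
            class = c("dii_registry", "data.frame"))
}

#' Load the default (synthetic) DII weight registry
#'
#' The shipped registry enumerates the 24 components of the adapted index.
#' Its weights are SYNTHETIC placeholders with plausible signs and
#' magnitudes (fiber, omega-3, vitamins positive; saturated fat and
#' cholesterol negative); substitute literature weights by editing the YAML
#' file or supplying your own registry.
#'
#' @param path YAML file; defaults to the registry shipped with the package
#' @return a `dii_registry`
#' @export
default_dii_registry <- function(path = system.file("extdata",
                                                    "dii_weights_synthetic.yaml",
                                                    package = "envgform")) {
  cfg <- yaml::read_yaml(path)
  comp <- vapply(cfg$components, `[[`, character(1), "name")
  w <- vapply(cfg$components, `[[`, numeric(1), "weight")
  ea <- vapply(cfg$components, `[[`, logical(1), "energy_adjust")
  dii_registry(comp, w, ea)
}

# Resolve the diet-component columns of a cohort/diet data frame for a
# registry; errors if any component column is absent.
diet_columns <- function(diet, registry, prefix = "diet_") {
  cols <- paste0(prefix, registry$component)
  missing <- setdiff(cols, names(diet))
  if (length(missing))
    stop("missing diet component column(s): ", paste(missing, collapse = ", "))
  cols
}

#' Energy-adjust component intakes
#'
#' Components flagged `energy_adjust` in the registry are rescaled to intake
#' per 1000 kcal (the density method); all other components pass through
#' unchanged.
#'
#' @param diet data frame with `diet_<component>` columns and a
#'   `diet_energy_kcal` column (plus optionally `id` for error messages)
#' @param registry a `dii_registry`
#' @return `diet` with the flagged columns rescaled
#' @export
energy_adjust <- function(diet, registry = default_dii_registry()) {
  cols <- diet_columns(diet, registry)
  energy <- diet$diet_energy_kcal
  if (is.null(energy)) stop("diet table lacks a diet_energy_kcal column")
  bad <- which(!(energy > 0))
  if (length(bad)) {
    who <- if (!is.null(diet$id)) diet$id[bad] else bad
    stop("non-positive energy for participant(s): ",
         paste(who, collapse = ", "))
  }
  for (i in which(registry$energy_adjust)) {
    diet[[cols[i]]] <- diet[[cols[i]]] / (energy / 1000)
  }
  diet
}

#' Standardize component intakes to weighted z-scores
#'
#' Per component, z = (x - weighted mean) / weighted SD with the population
#' (denominator-n) convention, so each z column has weighted mean 0 and
#' weighted SD 1. Standardization is invariant to rescaling all weights by
#' a constant.
#'
#' @param diet (energy-adjusted) diet data frame
#' @param weights positive survey weights, one per row
#' @param registry a `dii_registry`
#' @return numeric matrix of z-scores, one column per registry component
#' @export
standardize_intakes <- function(diet, weights = rep(1, nrow(diet)),
                                registry = default_dii_registry()) {
  stopifnot(nrow(diet) >= 2L, length(weights) == nrow(diet),
            all(weights > 0))
  cols <- diet_columns(diet, registry)
  u <- weights / sum(weights)
  z <- matrix(NA_real_, nrow(diet), length(cols),
              dimnames = list(NULL, registry$component))
  for (i in seq_along(cols)) {
    x <- diet[[cols[i]]]
    m <- sum(u * x)
    s <- sqrt(sum(u * (x - m)^2))
    if (!(s > 0)) stop("zero variance in component: ", registry$component[i])
    z[, i] <- (x - m) / s
  }
  z
}

#' Compute per-participant DII scores from z-scores
#'
#' score = s * sum_c weight_c * z_c with s = +1 under the `"paper"`
#' convention (positive = anti-inflammatory) and s = -1 under `"classic"`
#' (positive = pro-inflammatory). The score is linear in the z matrix and
#' flipping the convention negates every score exactly.
#'
#' @param z z-score matrix with one column per registry component
#' @param registry a `dii_registry`
#' @param sign_convention `"paper"` (default) or `"classic"`
#' @return numeric vector of scores
#' @export
compute_dii <- function(z, registry = default_dii_registry(),
                        sign_convention = c("paper", "classic")) {
  sign_convention <- match.arg(sign_convention)
  if (!identical(colnames(z), registry$component))
    stop("z-score columns do not match registry components")
  s <- if (sign_convention == "paper") 1 else -1
  drop(s * (z %*% registry$weight))
}

#' Construct a fruit/vegetable serving registry
#'
#' Maps coded food items to a group (`fruit`, `vegetable`, or `excluded`)
#' and a serving size in the item's recorded quantity units (grams here).
#' Mixed sweets whose main ingredient is not a fruit are carried as
#' `excluded` so their records contribute zero servings.
#'
#' @param food_code character codes (unique)
#' @param group one of fruit/vegetable/excluded per code
#' @param serving_size positive serving size per fruit/vegetable code
#' @return a data frame of class `serving_registry`
#' @export
serving_registry <- function(food_code, group, serving_size) {
  stopifnot(length(food_code) == length(group),
            length(group) == length(serving_size),
            !anyDuplicated(food_code),
            all(group %in% c("fruit", "vegetable", "excluded")))
  fv <- group %in% c("fruit", "vegetable")
  if (any(fv & !(serving_size > 0)))
    stop("fruit/vegetable codes require a positive serving size")
  structure(data.frame(food_code = as.character(food_code),
                       group = as.character(group),
                       serving_size = as.numeric(serving_size),
                       stringsAsFactors = FALSE),
            class = c("serving_registry", "data.frame"))
}

#' Load the default (synthetic) serving registry
#'
#' @param path YAML file; defaults to the registry shipped with the package
#' @return a `serving_registry`
#' @export
default_serving_registry <- function(path = system.file("extdata",
                                                        "serving_registry_synthetic.yaml",
                                                        package = "envgform")) {
  cfg <- yaml::read_yaml(path)
  serving_registry(vapply(cfg$foods, `[[`, character(1), "code"),
                   vapply(cfg$foods, `[[`, character(1), "group"),
                   vapply(cfg$foods, function(f)
                     as.numeric(f$serving_size %||% NA_real_), numeric(1)))
}

#' Daily fruit-and-vegetable servings from coded food records
#'
#' servings = sum over fruit/vegetable records of quantity / serving size;
#' records with `excluded` codes contribute zero. Unknown codes are an
#' error.
#'
#' @param records a data frame with columns `food_code` and `quantity`
#'   (possibly zero rows), or NULL/empty for no records
#' @param registry a `serving_registry`
#' @return servings per day (scalar)
#' @export
compute_fv_servings <- function(records, registry = default_serving_registry()) {
  if (is.null(records) || NROW(records) == 0L) return(0.0)
  stopifnot(all(c("food_code", "quantity") %in% names(records)))
  i <- match(records$food_code, registry$food_code)
  if (anyNA(i))
    stop("unknown food code(s): ",
         paste(unique(records$food_code[is.na(i)]), collapse = ", "))
  keep <- registry$group[i] != "excluded"
  sum(records$quantity[keep] / registry$serving_size[i][keep])
}

#' Append DII and FV-serving columns to a cohort
#'
#' Convenience wrapper running energy adjustment, weighted standardization,
#' DII scoring, and per-participant FV serving counts, appending `dii` and
#' `fv_servings` columns.
#'
#' @param cohort cohort data frame with diet columns and an `fv_records`
#'   list column
#' @param dii_reg a `dii_registry`
#' @param serving_reg a `serving_registry`
#' @param sign_convention passed to [compute_dii()]
#' @return the cohort with `dii` and `fv_servings` columns
#' @export
score_diet <- function(cohort, dii_reg = default_dii_registry(),
                       serving_reg = default_serving_registry(),
                       sign_convention = "paper") {
  adj <- energy_adjust(cohort, dii_reg)
  z <- standardize_intakes(adj, cohort$survey_weight, dii_reg)
  cohort$dii <- compute_dii(z, dii_reg, sign_convention)
  cohort$fv_servings <- vapply(cohort$fv_records, compute_fv_servings,
                               numeric(1), registry = serving_reg)
  cohort
}
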