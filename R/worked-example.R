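# Worked example: published aggregates from a large French dual-frame RDD
# health survey (2017; 25,319 dual-frame respondents of whom 15,602 were
# reached on a cell number).  The tables ship with the package as plain CSV
# and serve as deterministic inputs: every aggregate (variable-level D, mean
# D, mean deft, relative differences) can be recomputed from the printed
# category-level values with the package's own aggregation rules.

#' Load the worked-example survey tables
#'
#' Three tables from a published French dual-frame (landline + cell) versus
#' counterfactual single-frame (cell-only) design comparison:
#' `balance_categories` (reference shares and standardized distances per
#' category, design-weighted for the calibration covariates and
#' calibration-weighted for the external covariates), `balance_variables`
#' (the printed variable-level mean absolute distances D), and `health`
#' (prevalence, SE, deft and relative difference for seven health indicators,
#' overall and for the 18-30 and 60-75 age groups).
#'
#' @return list of data frames `balance_categories`, `balance_variables`,
#'   `health`.
#' @export
worked_example <- function() {
  path <- function(f) system.file("extdata", f, package = "rddframes",
                                  mustWork = TRUE)
  list(
    balance_categories = utils::read.csv(path("worked_example_balance_categories.csv")),
    balance_variables = utils::read.csv(path("worked_example_balance_variables.csv")),
    health = utils::read.csv(path("worked_example_health.csv"))
  )
}

#' Recompute the worked-example aggregates from the printed values
#'
#' Applies the package's aggregation rules to the worked-example tables at
#' printed precision: variable-level D as the mean absolute standardized
#' distance over categories ([variable_distance()]), sample-level mean D as
#' the mean of the variable-level values ([sample_distance()]), the mean deft
#' over the seven indicators, and relative differences from the printed
#' prevalence pairs ([relative_difference()]).  All results are rounded half
#' away from zero to the printed precision.
#'
#' @param example tables from [worked_example()].
#' @return list with `variable_D` (block, variable, recomputed D per design),
#'   `mean_D` (block, design, value), `mean_deft` (design, value) and
#'   `relative_differences` (scope, indicator, value).
#' @export
reconstruct_worked_example <- function(example = worked_example()) {
  cats <- example$balance_categories
  vars <- example$balance_variables

  groups <- split(cats, list(cats$block, cats$variable), drop = TRUE)
  per_var <- do.call(rbind, lapply(groups, function(g) {
    data.frame(block = g$block[1], variable = g$variable[1],
               D_df = round_half_up(variable_distance(g$d_df), 1),
               D_sf = round_half_up(variable_distance(g$d_sf), 1))
  }))
  rownames(per_var) <- NULL

  mean_D <- do.call(rbind, lapply(split(vars, vars$block), function(g) {
    data.frame(block = g$block[1],
               design = c("DF", "SF"),
               mean_D = round_half_up(c(sample_distance(g$D_df),
                                        sample_distance(g$D_sf)), 1))
  }))
  rownames(mean_D) <- NULL

  overall <- example$health[example$health$scope == "all", ]
  mean_deft <- data.frame(
    design = c("DF", "SF"),
    mean_deft = round_half_up(c(mean(overall$deft_df), mean(overall$deft_sf)), 2))

  rel <- example$health
  relative_differences <- data.frame(
    scope = rel$scope, indicator = rel$indicator,
    printed = rel$rel_diff,
    recomputed = round_half_up(relative_difference(rel$prev_sf, rel$prev_df), 1))

  list(variable_D = per_var, mean_D = mean_D, mean_deft = mean_deft,
       relative_differences = relative_differences)
}
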