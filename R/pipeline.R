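# End-to-end orchestration of the counterfactual design comparison.

#' Configuration of a full counterfactual experiment
#'
#' @param population a [population_config()] (its seed is re-derived from
#'   `seed` so one master seed controls the whole run).
#' @param fieldwork a [fieldwork_config()].
#' @param nonworking_rate_ll,nonworking_rate_cell frame non-working rates
#'   passed to [build_frames()].
#' @param margin_spec `"joint"` rakes sex and age as one cross-classified
#'   sex x age margin (12 cells); `"marginal"` rakes them separately.
#' @param indicators health indicator columns to estimate.
#' @param subgroups age subgroups for [compare_designs()].
#' @param external_variables person-level variables diagnosed with calibrated
#'   weights against their exact population shares (the gold-standard role).
#' @param seed master seed; per-stage streams are derived from it.
#' @return a `run_config` list.
#' @export
run_config <- function(population = population_config(),
                       fieldwork = fieldwork_config(dialed_budget = 10000),
                       nonworking_rate_ll = 0.50, nonworking_rate_cell = 0.33,
                       margin_spec = c("joint", "marginal"),
                       indicators = HEALTH_INDICATORS,
                       subgroups = list(all = NULL, "18-30" = c(18, 30),
                                        "60-75" = c(60, 75)),
                       external_variables = c("equipment", "daily_smoking"),
                       seed = 1L) {
  margin_spec <- match.arg(margin_spec)
  stopifnot(inherits(population, "population_config"),
            inherits(fieldwork, "fieldwork_config"))
  structure(list(population = population, fieldwork = fieldwork,
                 nonworking_rate_ll = nonworking_rate_ll,
                 nonworking_rate_cell = nonworking_rate_cell,
                 margin_spec = margin_spec, indicators = indicators,
                 subgroups = subgroups,
                 external_variables = external_variables,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; `population` and
#' `fieldwork` subtrees are passed to their constructors.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  pop <- do.call(population_config, if (is.null(y$population)) list() else y$population)
  fw <- do.call(fieldwork_config, if (is.null(y$fieldwork)) list() else y$fieldwork)
  args <- y[setdiff(names(y), c("population", "fieldwork"))]
  do.call(run_config, c(list(population = pop, fieldwork = fw), args))
}

#' Default study scenario
#'
#' The package's reference scenario: a scaled-down emulation of a national
#' dual-frame RDD health survey.  150,000 synthetic persons, 45,000 dialed
#' numbers at the conventional 40/60 landline/cell allocation, default
#' equipment gradients and non-working rates, yielding roughly 11,000
#' dual-frame completes of which two thirds form the counterfactual
#' single-frame sample.
#'
#' @param seed master seed.
#' @param population_size,dialed_budget scale parameters.
#' @return a [run_config()].
#' @export
study_config <- function(seed = 1L, population_size = 150000,
                         dialed_budget = 45000) {
  run_config(population = population_config(population_size = population_size),
             fieldwork = fieldwork_config(dialed_budget = dialed_budget),
             seed = seed)
}

calibration_variables <- function(margin_spec) {
  if (margin_spec == "joint") {
    c("sex_age", "education", "hh_size", "urbanization", "region")
  } else {
    c("sex", "age_band", "education", "hh_size", "urbanization", "region")
  }
}

#' Run the full counterfactual experiment
#'
#' Simulates the population, frames and fieldwork, computes dual-frame and
#' counterfactual single-frame design weights, calibrates both by raking to
#' the population margins, and produces balance reports (design weights on
#' calibration covariates, calibrated weights on external covariates),
#' R-indicators, AAPOR outcome rates, weight-dispersion summaries, and the
#' design-comparison estimate report (overall and by age subgroup), together
#' with the true population prevalences for bias assessment.
#'
#' @param config a [run_config()] or a YAML path for [read_run_config()].
#' @param output_dir optional directory; when given, all artifacts are
#'   written as flat CSV/JSON stamped with the seed and a config hash.
#' @param population optional pre-generated `synthetic_population` (used by
#'   [replicate_study()] to hold the population fixed across replicates).
#' @param fieldwork_seed optional override of the fieldwork stream seed.
#' @return a `frame_experiment` list; see Details in the package vignette.
#' @export
run_experiment <- function(config, output_dir = NULL, population = NULL,
                           fieldwork_seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))

  pop_cfg <- config$population
  pop_cfg$seed <- child_seed(config$seed, "population")
  if (is.null(population)) population <- generate_population(pop_cfg)

  frames <- build_frames(population, config$nonworking_rate_ll,
                         config$nonworking_rate_cell)
  cal_vars <- calibration_variables(config$margin_spec)
  margins <- reference_margins(population, cal_vars)
  ext_margins <- reference_margins(population, config$external_variables)

  fw <- config$fieldwork
  fw$seed <- if (is.null(fieldwork_seed)) child_seed(config$seed, "fieldwork")
             else fieldwork_seed
  field <- simulate_calls(draw_numbers_seeded(frames, fw), population, frames, fw)
  resp <- field$respondents

  pi_df <- df_selection_probability(resp, frames, fw)
  w_df <- weight_set("DF", resp$person_id, 1 / pi_df)
  sf <- build_counterfactual_sf(resp, frames, fw)

  n_pop <- nrow(population$persons)
  rk_df <- rake(w_df$weight, resp, margins, population_total = n_pop)
  rk_sf <- rake(sf$weights$weight, sf$respondents, margins,
                population_total = n_pop)

  balance <- list(
    DF = balance_report(resp, w_df$weight, margins),
    SF = balance_report(sf$respondents, sf$weights$weight, margins),
    DF_external = balance_report(resp, rk_df$weights, ext_margins),
    SF_external = balance_report(sf$respondents, rk_sf$weights, ext_margins)
  )

  rind <- list(
    DF = r_indicator(resp, population$persons, cal_vars,
                     sample_weights = w_df$weight),
    SF = r_indicator(sf$respondents, population$persons, cal_vars,
                     sample_weights = sf$weights$weight)
  )

  estimates <- compare_designs(resp, rk_df$weights,
                               sf$respondents, rk_sf$weights,
                               indicators = config$indicators,
                               subgroups = config$subgroups)
  rates <- outcome_rates(field$dispositions)

  truth <- population_truth(population, config$indicators, config$subgroups)

  out <- structure(list(
    config = config, seed = config$seed,
    population_size = n_pop, frames = frames,
    fieldwork = field,
    respondents = resp, sf_respondents = sf$respondents,
    design_weights = list(DF = w_df, SF = sf$weights),
    raking = list(DF = rk_df, SF = rk_sf),
    dispersion = list(
      DF_design = weight_dispersion(w_df$weight),
      SF_design = weight_dispersion(sf$weights$weight),
      DF_calibrated = weight_dispersion(rk_df$weights),
      SF_calibrated = weight_dispersion(rk_sf$weights)),
    balance = balance, r_indicators = rind,
    estimates = estimates, outcome_rates = rates,
    truth = truth
  ), class = "frame_experiment")

  if (!is.null(output_dir)) write_experiment(out, output_dir)
  out
}

# draw_numbers with the fieldwork stream seed applied, so that
# simulate_calls() re-seeds deterministically afterwards.
draw_numbers_seeded <- function(frames, config) {
  set.seed(child_seed(config$seed, 7L))
  draw_numbers(frames, config)
}

# True prevalences on the population and its coverage strata, per scope.
population_truth <- function(population, indicators, subgroups) {
  p <- population$persons
  rows <- list()
  for (sg in names(subgroups)) {
    rng <- subgroups[[sg]]
    keep <- if (is.null(rng)) rep(TRUE, nrow(p)) else
      p$age >= rng[1] & p$age <= rng[2]
    covered_cell <- keep & p$n_cell > 0
    for (ind in indicators) {
      rows[[length(rows) + 1L]] <- data.frame(
        scope = sg, indicator = ind,
        population = mean(p[[ind]][keep]),
        cell_covered = mean(p[[ind]][covered_cell]))
    }
  }
  do.call(rbind, rows)
}

#' @export
print.frame_experiment <- function(x, ...) {
  cat(sprintf("Counterfactual dual-frame experiment (seed %d)\n", x$seed))
  cat(sprintf("  population %d; respondents DF %d (SF subset %d)\n",
              x$population_size, nrow(x$respondents), nrow(x$sf_respondents)))
  r <- x$outcome_rates
  cat("  AAPOR RR3:", paste(sprintf("%s %.1f%%", r$frame, 100 * r$rr3),
                            collapse = ", "), "\n")
  cat(sprintf("  mean D (design weights): DF %.1f, SF %.1f\n",
              round_half_up(x$balance$DF$mean_D, 1),
              round_half_up(x$balance$SF$mean_D, 1)))
  cat(sprintf("  R-indicator: DF %.3f, SF %.3f\n",
              x$r_indicators$DF$R, x$r_indicators$SF$R))
  cat(sprintf("  calibrated weight CV: DF %.2f, SF %.2f; max/min DF %.1f, SF %.1f\n",
              x$dispersion$DF_calibrated$cv, x$dispersion$SF_calibrated$cv,
              x$dispersion$DF_calibrated$max_min_ratio,
              x$dispersion$SF_calibrated$max_min_ratio))
  ov <- x$estimates[x$estimates$scope == "all", ]
  cat(sprintf("  mean deft: DF %.2f, SF %.2f\n",
              mean(ov$deft_df), mean(ov$deft_sf)))
  invisible(x)
}

#' Replicate the fieldwork to measure Monte-Carlo properties
#'
#' Holds the synthetic population (and frames) fixed and repeats the
#' fieldwork with independent seeds, re-running weighting and calibration
#' each time.  Summarizes, per indicator and design, the mean estimate, the
#' empirical SE, the bias against the synthetic truth (whole population for
#' DF, cell-covered subpopulation for SF), and the coverage of +/- 2 SE
#' intervals built from each replicate's linearized SE.
#'
#' @param config a [run_config()].
#' @param n_replicates number of fieldwork replicates (>= 2; with 1 the
#'   single-run report of [run_experiment()] is returned unchanged).
#' @param calibrated if `FALSE`, summarize design-weighted estimates instead
#'   of calibrated ones.
#' @return a `replicate_summary` data frame.
#' @export
replicate_study <- function(config, n_replicates, calibrated = TRUE) {
  stopifnot(inherits(config, "run_config"), n_replicates >= 1)
  if (n_replicates == 1) return(run_experiment(config))
  pop_cfg <- config$population
  pop_cfg$seed <- child_seed(config$seed, "population")
  population <- generate_population(pop_cfg)

  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    ex <- run_experiment(config, population = population,
                         fieldwork_seed = child_seed(config$seed, 100L + r))
    est <- ex$estimates[ex$estimates$scope == "all", ]
    if (!calibrated) {
      est <- within_design_estimates(ex, config$indicators)
    }
    est$replicate <- r
    reps[[r]] <- merge(est, ex$truth[ex$truth$scope == "all",
                                     c("indicator", "population", "cell_covered")],
                       by = "indicator")
  }
  all <- do.call(rbind, reps)
  summ <- do.call(rbind, lapply(split(all, all$indicator), function(g) {
    data.frame(
      indicator = g$indicator[1],
      truth_population = g$population[1],
      truth_cell_covered = g$cell_covered[1],
      mean_df = mean(g$prev_df), se_emp_df = sd(g$prev_df),
      bias_df = mean(g$prev_df) - g$population[1],
      coverage_df = mean(abs(g$prev_df - g$population[1]) <= 2 * g$se_df),
      mean_sf = mean(g$prev_sf), se_emp_sf = sd(g$prev_sf),
      bias_sf = mean(g$prev_sf) - g$cell_covered[1],
      coverage_sf = mean(abs(g$prev_sf - g$cell_covered[1]) <= 2 * g$se_sf))
  }))
  rownames(summ) <- NULL
  structure(summ, class = c("replicate_summary", "data.frame"),
            n_replicates = n_replicates)
}

# design-weighted (uncalibrated) overall estimates of one experiment
within_design_estimates <- function(ex, indicators) {
  rows <- lapply(indicators, function(ind) {
    df <- weighted_prevalence(ex$respondents[[ind]], ex$design_weights$DF$weight)
    sf <- weighted_prevalence(ex$sf_respondents[[ind]], ex$design_weights$SF$weight)
    data.frame(scope = "all", indicator = ind,
               prev_df = df$estimate, se_df = df$se,
               prev_sf = sf$estimate, se_sf = sf$se)
  })
  do.call(rbind, rows)
}

## ---- artifact output ----------------------------------------------------

# Polynomial rolling hash of the deparsed configuration, for stamping artifacts.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write all experiment artifacts to a directory
#'
#' Flat CSV/JSON files: respondent weights (design + calibrated), balance
#' reports, estimate report, disposition and outcome-rate tables, raking and
#' dispersion summaries, and a `run.json` stamp with the seed and config
#' hash.
#'
#' @param experiment a `frame_experiment`.
#' @param output_dir directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_experiment <- function(experiment, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(output_dir, f)
  wcsv <- function(d, f) utils::write.csv(d, p(f), row.names = FALSE)

  wcsv(data.frame(respondent_id = experiment$design_weights$DF$respondent_id,
                  design_label = "DF",
                  design_weight = experiment$design_weights$DF$weight,
                  calibrated_weight = experiment$raking$DF$weights),
       "weights_df.csv")
  wcsv(data.frame(respondent_id = experiment$design_weights$SF$respondent_id,
                  design_label = "SF",
                  design_weight = experiment$design_weights$SF$weight,
                  calibrated_weight = experiment$raking$SF$weights),
       "weights_sf.csv")
  for (nm in names(experiment$balance)) {
    wcsv(experiment$balance[[nm]]$categories,
         sprintf("balance_%s_categories.csv", tolower(nm)))
    wcsv(experiment$balance[[nm]]$variables,
         sprintf("balance_%s_variables.csv", tolower(nm)))
  }
  wcsv(as.data.frame(experiment$estimates), "estimates.csv")
  wcsv(experiment$fieldwork$dispositions, "dispositions.csv")
  wcsv(experiment$outcome_rates, "outcome_rates.csv")
  wcsv(experiment$truth, "population_truth.csv")

  jsonlite::write_json(list(
    seed = experiment$seed,
    config_hash = config_hash(experiment$config),
    population_size = experiment$population_size,
    raking = lapply(experiment$raking, function(r)
      r[c("iterations", "max_deviation", "converged")]),
    dispersion = experiment$dispersion,
    r_indicators = lapply(experiment$r_indicators, function(r)
      r[c("R", "propensity_sd", "model")]),
    mean_D = lapply(experiment$balance, function(b) b$mean_D)
  ), p("run.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}
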