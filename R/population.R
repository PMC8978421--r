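# Synthetic population: demographics, households, telephone equipment,
# latent health indicators and response propensities.

AGE_BANDS <- c("18-24", "25-34", "35-44", "45-54", "55-64", "65-75")
AGE_LOWER <- c(18L, 25L, 35L, 45L, 55L, 65L)
AGE_UPPER <- c(24L, 34L, 44L, 54L, 64L, 75L)

EDUCATION_LEVELS <- c("primary", "less_than_high_school", "high_school",
                      "post_secondary_2y", "post_secondary_3_4y",
                      "post_secondary_5y_plus")
HH_SIZE_LEVELS <- c("1", "2", "3", "4", "5+")
URBANIZATION_LEVELS <- c("rural", "lt_20k", "20k_100k", "100k_200k",
                         "ge_200k", "paris")
REGION_LEVELS <- c("IDF", "Grand-Est", "Hauts-de-France", "Normandie",
                   "Centre", "Bourgogne-FC", "Bretagne", "Pays-de-Loire",
                   "Nouvelle-Aquitaine", "ARA", "Occitanie", "PACA-Corse")
EQUIPMENT_CLASSES <- c("phoneless", "landline_only", "cell_only", "both")

HEALTH_INDICATORS <- c("poor_health", "chronic_disease", "activity_limitation",
                       "obesity", "physical_inactivity", "daily_smoking",
                       "suicide_attempt")

#' Configuration of the synthetic population generator
#'
#' Builds a validated configuration for [generate_population()].  Defaults
#' emulate the French adult (18-75) population as seen by a national
#' telephone health survey: category shares follow published labor-force
#' margins, cell-phone ownership is close to 96\% overall and decreases with
#' age while increasing with education, and landline ownership (a household
#' attribute) is close to 77\% overall and increases with age.
#'
#' @param population_size number of persons to generate (all aged 18-75,
#'   the survey's eligibility range).
#' @param category_shares named list of share vectors for `sex`, `age`,
#'   `education`, `hh_size`, `urbanization`, `region`.  Each vector is
#'   normalized to sum to 1 (printed margins often carry rounding residue).
#'   Sex and age may also be given jointly as a 2 x 6 `sex_age` matrix;
#'   by default the joint distribution is the product of the two margins.
#' @param equipment_model list with `cell_age` (P(cell) per age band, logit
#'   scale applied with `cell_edu_logit` shifts per education level) and
#'   `landline_age` (P(household landline) per age band of the oldest
#'   member).
#' @param n_phone_numbers distribution of numbers owned per equipped frame,
#'   a named share vector over counts `1`, `2`, `3`.
#' @param health_model per-indicator list with `baseline` prevalence and
#'   log-odds shifts `age_logit`, `edu_logit` and `equipment_logit` (the
#'   latter a residual effect of telephone-equipment class beyond
#'   demographics, nonzero by default for daily smoking and lifetime
#'   suicide attempt).
#' @param response_model contact/cooperation parameters used by
#'   [simulate_calls()]: per-attempt contact probability per age band and
#'   frame, cooperation probability per frame, probability of a partial
#'   interview, probability of reaching a Kish selectee who did not answer
#'   the phone, and the fraction of never-answered numbers coded as
#'   unknown-eligibility.
#' @param misreport_prob probability that an interviewed person misreports a
#'   phone-multiplicity count by one (default 0: reported counts equal true
#'   counts).  Reported counts never drop below 1 for the frame of origin.
#' @param seed integer seed controlling all generator randomness.
#' @return a `population_config` list.
#' @export
population_config <- function(population_size = 10000,
                              category_shares = NULL,
                              equipment_model = NULL,
                              n_phone_numbers = c("1" = 0.9, "2" = 0.09, "3" = 0.01),
                              health_model = NULL,
                              response_model = NULL,
                              misreport_prob = 0,
                              seed = 1L) {
  if (misreport_prob < 0 || misreport_prob > 1) {
    stop("misreport_prob must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(population_size) || length(population_size) != 1 ||
      population_size < 1) {
    stop("population_size must be a positive integer", call. = FALSE)
  }
  shares <- default_category_shares()
  if (!is.null(category_shares)) {
    for (nm in names(category_shares)) shares[[nm]] <- category_shares[[nm]]
  }
  for (nm in setdiff(names(shares), "sex_age")) {
    s <- shares[[nm]]
    if (any(!is.finite(s)) || any(s < 0)) {
      stop(sprintf("invalid %s shares", nm), call. = FALSE)
    }
    shares[[nm]] <- s / sum(s)
    check_shares(shares[[nm]], nm)
  }
  if (is.null(shares$sex_age)) {
    shares$sex_age <- outer(shares$sex, shares$age)
    dimnames(shares$sex_age) <- list(names(shares$sex), names(shares$age))
  }
  shares$sex_age <- shares$sex_age / sum(shares$sex_age)

  equip <- default_equipment_model()
  if (!is.null(equipment_model)) {
    for (nm in names(equipment_model)) equip[[nm]] <- equipment_model[[nm]]
  }
  for (p in c(equip$cell_age, equip$landline_age)) {
    if (!is.finite(p) || p < 0 || p > 1) {
      stop("equipment probabilities must lie in [0, 1]", call. = FALSE)
    }
  }

  n_phone_numbers <- n_phone_numbers / sum(n_phone_numbers)
  check_shares(n_phone_numbers, "phone-count")

  hm <- default_health_model()
  if (!is.null(health_model)) {
    for (nm in names(health_model)) hm[[nm]] <- health_model[[nm]]
  }
  rm_ <- default_response_model()
  if (!is.null(response_model)) {
    for (nm in names(response_model)) rm_[[nm]] <- response_model[[nm]]
  }

  structure(list(population_size = as.integer(population_size),
                 category_shares = shares,
                 equipment_model = equip,
                 n_phone_numbers = n_phone_numbers,
                 health_model = hm,
                 response_model = rm_,
                 misreport_prob = misreport_prob,
                 seed = as.integer(seed)),
            class = "population_config")
}

default_category_shares <- function() {
  list(
    sex = c(male = 0.487, female = 0.513),
    age = stats::setNames(c(0.112, 0.171, 0.185, 0.195, 0.182, 0.155), AGE_BANDS),
    education = stats::setNames(c(0.133, 0.354, 0.204, 0.128, 0.076, 0.105),
                                EDUCATION_LEVELS),
    hh_size = stats::setNames(c(0.174, 0.342, 0.189, 0.193, 0.102),
                              HH_SIZE_LEVELS),
    urbanization = stats::setNames(c(0.240, 0.168, 0.121, 0.049, 0.257, 0.166),
                                   URBANIZATION_LEVELS),
    region = stats::setNames(c(0.190, 0.086, 0.093, 0.051, 0.040, 0.044, 0.051,
                               0.057, 0.092, 0.122, 0.091, 0.083),
                             REGION_LEVELS),
    sex_age = NULL
  )
}

default_equipment_model <- function() {
  list(
    # P(cell) at the reference education level, per age band; the overall
    # marginal lands near 0.96 with the education shifts applied.
    cell_age = stats::setNames(c(0.995, 0.99, 0.98, 0.97, 0.94, 0.87), AGE_BANDS),
    # log-odds shift by education level (increases with education)
    cell_edu_logit = stats::setNames(c(-0.9, -0.3, 0, 0.3, 0.6, 0.8),
                                     EDUCATION_LEVELS),
    # P(household owns a landline) per age band of the oldest member;
    # person-level coverage lands near 0.77.
    landline_age = stats::setNames(c(0.50, 0.60, 0.74, 0.83, 0.90, 0.94),
                                   AGE_BANDS)
  )
}

default_health_model <- function() {
  z <- rep(0, 6)
  eq0 <- stats::setNames(rep(0, 4), EQUIPMENT_CLASSES)
  ind <- function(baseline, age_logit = z, edu_logit = z, equipment_logit = eq0) {
    list(baseline = baseline,
         age_logit = stats::setNames(age_logit, AGE_BANDS),
         edu_logit = stats::setNames(edu_logit, EDUCATION_LEVELS),
         equipment_logit = equipment_logit)
  }
  smoke_eq <- eq0; smoke_eq[["cell_only"]] <- 0.15; smoke_eq[["landline_only"]] <- -0.15
  suic_eq <- eq0; suic_eq[["cell_only"]] <- 0.15; suic_eq[["landline_only"]] <- -0.10
  list(
    poor_health = ind(0.060, c(-1.2, -0.8, -0.3, 0.2, 0.5, 0.7),
                      c(0.6, 0.3, 0, -0.2, -0.3, -0.4)),
    chronic_disease = ind(0.366, c(-0.9, -0.6, -0.3, 0.1, 0.5, 0.8),
                          c(0.2, 0.1, 0, -0.1, -0.1, -0.2)),
    activity_limitation = ind(0.216, c(-0.9, -0.5, -0.2, 0.1, 0.4, 0.7),
                              c(0.3, 0.1, 0, -0.1, -0.2, -0.3)),
    obesity = ind(0.135, c(-0.8, -0.4, -0.1, 0.2, 0.4, 0.5),
                  c(0.5, 0.3, 0, -0.1, -0.3, -0.5)),
    physical_inactivity = ind(0.087, c(-0.2, -0.1, 0, 0, 0.1, 0.1),
                              c(0.3, 0.1, 0, -0.1, -0.2, -0.3)),
    daily_smoking = ind(0.270, c(0.4, 0.3, 0.1, 0, -0.5, -1.0),
                        c(0.4, 0.3, 0.1, -0.1, -0.3, -0.5),
                        equipment_logit = smoke_eq),
    suicide_attempt = ind(0.072, z, c(0.2, 0.1, 0, -0.1, -0.1, -0.2),
                          equipment_logit = suic_eq)
  )
}

default_response_model <- function() {
  list(
    # per-call-attempt contact probability, by age band
    contact_cell = stats::setNames(c(0.10, 0.10, 0.11, 0.12, 0.14, 0.15),
                                   AGE_BANDS),
    contact_landline = stats::setNames(c(0.07, 0.08, 0.09, 0.11, 0.13, 0.14),
                                       AGE_BANDS),
    cooperation_cell = 0.45,
    cooperation_landline = 0.50,
    partial_prob = 0.02,
    recontact_prob = 0.90,
    unknown_frac = 0.35
  )
}

#' Generate a synthetic population with households and telephone equipment
#'
#' Persons are drawn from the configured category shares (sex by age jointly;
#' education, urbanization, region independently).  Households are formed by
#' grouping persons within each household-size category after ordering by age
#' with noise, which induces intra-household age correlation (couple-like
#' pairing) so that the number of eligible persons per landline household
#' varies realistically.  Landline ownership is assigned at household level
#' from the age of the oldest member; cell ownership at person level from the
#' age x education gradient.  Latent health indicators follow a logistic
#' model on age, education and (residually) telephone-equipment class.
#'
#' @param config a [population_config()].
#' @return a `synthetic_population` list with elements `persons` (one row per
#'   person), `households` (one row per household) and `config`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  set.seed(child_seed(config$seed, "population"))
  n <- config$population_size
  sh <- config$category_shares

  joint <- sh$sex_age
  cells <- expand.grid(sex = rownames(joint), age_band = colnames(joint),
                       stringsAsFactors = FALSE)
  cell_idx <- sample.int(nrow(cells), n, replace = TRUE, prob = as.vector(joint))
  sex <- cells$sex[cell_idx]
  age_band <- cells$age_band[cell_idx]
  band_i <- match(age_band, AGE_BANDS)
  age <- AGE_LOWER[band_i] +
    floor(runif(n) * (AGE_UPPER[band_i] - AGE_LOWER[band_i] + 1L))

  education <- sample(EDUCATION_LEVELS, n, replace = TRUE, prob = sh$education)
  urbanization <- sample(URBANIZATION_LEVELS, n, replace = TRUE,
                         prob = sh$urbanization)
  region <- sample(REGION_LEVELS, n, replace = TRUE, prob = sh$region)
  hh_size_cat <- sample(HH_SIZE_LEVELS, n, replace = TRUE, prob = sh$hh_size)

  # Household formation: within each size category, order persons by age with
  # noise and chunk consecutive persons into households of that size.  The
  # final (possibly short) chunk is kept as a household of its actual size.
  household_id <- integer(n)
  next_hh <- 1L
  sizes <- c(1L, 2L, 3L, 4L, 5L)
  for (k in seq_along(HH_SIZE_LEVELS)) {
    idx <- which(hh_size_cat == HH_SIZE_LEVELS[k])
    if (!length(idx)) next
    s <- sizes[k]
    ord <- idx[order(match(age_band[idx], AGE_BANDS) + runif(length(idx), 0, 2))]
    grp <- next_hh + (seq_along(ord) - 1L) %/% s
    household_id[ord] <- grp
    next_hh <- max(grp) + 1L
  }
  hh_actual_size <- as.vector(table(household_id)[as.character(household_id)])

  # Equipment: landline at household level (oldest member's age band), cell at
  # person level (age band baseline + education log-odds shift).
  eq <- config$equipment_model
  hh_max_band <- tapply(band_i, household_id, max)
  p_ll_hh <- eq$landline_age[hh_max_band]
  owns_ll_hh <- rbinom(length(p_ll_hh), 1, p_ll_hh) == 1
  names(owns_ll_hh) <- names(hh_max_band)

  p_cell <- plogis(qlogis(pmin(pmax(eq$cell_age[band_i], 1e-6), 1 - 1e-6)) +
                     eq$cell_edu_logit[education])
  # degenerate band probabilities stay exact (education shifts do not apply)
  p_cell[eq$cell_age[band_i] %in% c(0, 1)] <- eq$cell_age[band_i][eq$cell_age[band_i] %in% c(0, 1)]
  owns_cell <- rbinom(n, 1, p_cell) == 1

  counts <- as.integer(names(config$n_phone_numbers))
  draw_counts <- function(m) sample(counts, m, replace = TRUE,
                                    prob = config$n_phone_numbers)
  n_ll_hh <- ifelse(owns_ll_hh, NA_integer_, 0L)
  n_ll_hh[owns_ll_hh] <- draw_counts(sum(owns_ll_hh))
  n_cell <- integer(n)
  n_cell[owns_cell] <- draw_counts(sum(owns_cell))

  hh_has_ll <- owns_ll_hh[as.character(household_id)]
  equipment <- ifelse(hh_has_ll & owns_cell, "both",
               ifelse(hh_has_ll, "landline_only",
               ifelse(owns_cell, "cell_only", "phoneless")))

  persons <- data.frame(
    person_id = seq_len(n),
    household_id = household_id,
    sex = sex, age_band = age_band, age = age,
    sex_age = paste(sex, age_band, sep = "."),
    education = education, hh_size = hh_size_cat,
    urbanization = urbanization, region = region,
    equipment = equipment,
    n_cell = n_cell,
    n_landline = as.integer(n_ll_hh[as.character(household_id)]),
    e_ll = hh_actual_size,
    e_cell = 1L,
    stringsAsFactors = FALSE
  )

  # Latent health indicators: logistic in age, education, equipment class.
  # The intercept is re-centred so the population prevalence tracks the
  # configured baseline despite non-centred category effects.
  age_shares_real <- tabulate(band_i, 6) / n
  edu_shares_real <- weighted_shares(education, rep(1, n), EDUCATION_LEVELS)
  for (nm in names(config$health_model)) {
    m <- config$health_model[[nm]]
    icpt <- qlogis(m$baseline) -
      sum(age_shares_real * m$age_logit) -
      sum(edu_shares_real * m$edu_logit)
    p <- plogis(icpt + m$age_logit[age_band] + m$edu_logit[education] +
                  m$equipment_logit[equipment])
    persons[[nm]] <- rbinom(n, 1, p)
  }

  # Response propensities carried on records so fieldwork is reproducible.
  rmod <- config$response_model
  persons$contact_cell <- rmod$contact_cell[age_band]
  persons$coop_cell <- rep(rmod$cooperation_cell, n)
  persons$coop_landline <- rep(rmod$cooperation_landline, n)

  households <- data.frame(
    household_id = as.integer(names(hh_max_band)),
    size = as.vector(table(household_id)),
    max_age_band = AGE_BANDS[hh_max_band],
    owns_landline = as.vector(owns_ll_hh),
    n_landline = as.integer(n_ll_hh),
    contact_landline = as.vector(rmod$contact_landline[hh_max_band]),
    stringsAsFactors = FALSE
  )

  structure(list(persons = persons, households = households, config = config),
            class = "synthetic_population")
}

#' @export
print.synthetic_population <- function(x, ...) {
  p <- x$persons
  cat(sprintf("Synthetic population: %d persons in %d households\n",
              nrow(p), nrow(x$households)))
  cat(sprintf("  cell ownership %.1f%%, landline coverage %.1f%%\n",
              100 * mean(p$n_cell > 0), 100 * mean(p$n_landline > 0)))
  cat("  equipment classes:",
      paste(sprintf("%s %.1f%%", names(table(p$equipment)),
                    100 * as.vector(table(p$equipment)) / nrow(p)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Model-implied telephone equipment rates
#'
#' Exact marginal cell-ownership probability implied by a configuration,
#' obtained by summation over the age x education strata (the two are
#' independent in the generator).  Used as the analytic benchmark for the
#' realized ownership share of a generated population.
#'
#' @param config a [population_config()].
#' @return list with `cell` (exact marginal P(owns cell)).
#' @export
implied_equipment_rates <- function(config) {
  sh <- config$category_shares
  eq <- config$equipment_model
  age_sh <- colSums(sh$sex_age)
  p <- 0
  for (a in seq_along(AGE_BANDS)) {
    base <- qlogis(pmin(pmax(eq$cell_age[a], 1e-6), 1 - 1e-6))
    p <- p + age_sh[a] * sum(sh$education * plogis(base + eq$cell_edu_logit))
  }
  list(cell = unname(p))
}

#' Build the telephone sampling frames
#'
#' The sampling frame is the list of generated telephone numbers: every owned
#' landline number is attached to its household and every owned cell number
#' to its person, then unassigned (non-working) numbers are appended so the
#' frame attains the configured non-working rates.  Frame sizes are
#' `N = round(working / (1 - nonworking_rate))` per frame.
#'
#' @param population a `synthetic_population`.
#' @param nonworking_rate_ll,nonworking_rate_cell fraction of frame numbers
#'   that are non-working (defaults 0.50 landline, 0.33 cell, the rates
#'   observed in French RDD practice).
#' @return a `frame_spec` list with `ll` and `cell` number tables (non-working
#'   numbers have `NA` owners), totals `N_ll`, `N_cell`, and the rates.
#' @export
build_frames <- function(population, nonworking_rate_ll = 0.50,
                         nonworking_rate_cell = 0.33) {
  stopifnot(inherits(population, "synthetic_population"))
  for (r in c(nonworking_rate_ll, nonworking_rate_cell)) {
    if (!is.finite(r) || r < 0 || r > 1) {
      stop("non-working rates must lie in [0, 1]", call. = FALSE)
    }
  }
  hh <- population$households
  own <- hh[hh$owns_landline, ]
  ll_owner <- rep(own$household_id, own$n_landline)
  cell_owner <- with(population$persons,
                     rep(person_id, n_cell))

  frame_table <- function(owner, rate, frame) {
    w <- length(owner)
    if (rate >= 1 && w > 0) {
      stop(sprintf("non-working rate of 1 with %d owned %s numbers", w, frame),
           call. = FALSE)
    }
    N <- if (w == 0) 0L else as.integer(round(w / (1 - rate)))
    data.frame(number_id = seq_len(N),
               owner_id = c(owner, rep(NA_integer_, N - w)),
               working = c(rep(TRUE, w), rep(FALSE, N - w)))
  }
  ll <- frame_table(ll_owner, nonworking_rate_ll, "landline")
  cell <- frame_table(cell_owner, nonworking_rate_cell, "cell")

  structure(list(ll = ll, cell = cell,
                 N_ll = nrow(ll), N_cell = nrow(cell),
                 nonworking_rate_ll = nonworking_rate_ll,
                 nonworking_rate_cell = nonworking_rate_cell),
            class = "frame_spec")
}

#' @export
print.frame_spec <- function(x, ...) {
  cat(sprintf("Telephone frames: %d landline numbers (%.0f%% non-working), %d cell numbers (%.0f%% non-working)\n",
              x$N_ll, 100 * x$nonworking_rate_ll,
              x$N_cell, 100 * x$nonworking_rate_cell))
  invisible(x)
}

#' A reference margin table
#'
#' @param variable variable name.
#' @param categories unique ordered category labels.
#' @param shares population share per category; must sum to 1.
#' @return a `margin_table` data frame with columns `category`, `share`.
#' @export
margin_table <- function(variable, categories, shares) {
  if (anyDuplicated(categories)) {
    stop("margin categories must be unique", call. = FALSE)
  }
  if (length(categories) != length(shares)) {
    stop("categories and shares differ in length", call. = FALSE)
  }
  check_shares(shares, variable)
  structure(data.frame(category = as.character(categories),
                       share = as.numeric(shares),
                       stringsAsFactors = FALSE),
            variable = variable, class = c("margin_table", "data.frame"))
}

#' Exact population margins for calibration and balance benchmarks
#'
#' Category shares computed on the full synthetic population.  These play the
#' role of the external reference source (labor-force survey or census): they
#' are the raking targets and the `p_A` column of balance reports.
#'
#' @param population a `synthetic_population`.
#' @param variables character vector of person-level variables; defaults to
#'   the five calibration covariates with sex and age cross-classified.
#' @return named list of [margin_table()]s.
#' @export
reference_margins <- function(population,
                              variables = c("sex_age", "education", "hh_size",
                                            "urbanization", "region")) {
  stopifnot(inherits(population, "synthetic_population"))
  p <- population$persons
  lapply(stats::setNames(variables, variables), function(v) {
    if (!v %in% names(p)) {
      stop(sprintf("unknown margin variable '%s'", v), call. = FALSE)
    }
    lev <- variable_levels(v, p)
    margin_table(v, lev, as.vector(table(factor(p[[v]], levels = lev))) / nrow(p))
  })
}

# Canonical category order for the standard variables; observed order otherwise.
variable_levels <- function(v, data) {
  switch(v,
         sex = c("male", "female"),
         age_band = AGE_BANDS,
         sex_age = as.vector(outer(c("male", "female"), AGE_BANDS, paste, sep = ".")),
         education = EDUCATION_LEVELS,
         hh_size = HH_SIZE_LEVELS,
         urbanization = URBANIZATION_LEVELS,
         region = REGION_LEVELS,
         equipment = EQUIPMENT_CLASSES,
         sort(unique(as.character(data[[v]]))))
}
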