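# Design weights for the dual-frame design and the counterfactual
# single-frame (cell-only) design.

#' Dual-frame selection probability
#'
#' For an eligible person i reachable through `t_ll` landline numbers shared
#' with `e_ll` eligible household members and `t_cell` personal cell numbers,
#' the overlapping dual-frame selection probability is
#' \deqn{\pi_i^{df} = \frac{n_{LL}}{N_{LL}} \frac{t_{LL}^i}{e_{LL}^i}
#'   + \frac{n_C}{N_C} \frac{t_C^i}{e_C^i},}
#' with \eqn{e_C^i = 1}: the landline route is two-stage (number, then Kish
#' selection among the `e_ll` eligibles) and the cell route one-stage.
#' A frame in which the person owns no number contributes 0.
#'
#' @param respondents respondent records (one row per complete interview)
#'   with columns `t_ll`, `t_cell`, `e_ll`.
#' @param frames a `frame_spec` (for `N_ll`, `N_cell`).
#' @param config a [fieldwork_config()] (for `n_ll`, `n_cell`).
#' @param multiplicity_cap reported phone counts above the cap are truncated
#'   (default 3), the usual guard against extreme weights.
#' @return numeric vector of selection probabilities.
#' @export
df_selection_probability <- function(respondents, frames, config,
                                     multiplicity_cap = 3L) {
  t_ll <- pmin(respondents$t_ll, multiplicity_cap)
  t_cell <- pmin(respondents$t_cell, multiplicity_cap)
  e_ll <- respondents$e_ll
  if (any(t_ll > 0 & (is.na(e_ll) | e_ll < 1))) {
    stop("landline numbers reported with no eligible household member",
         call. = FALSE)
  }
  ll_term <- ifelse(t_ll > 0, (config$n_ll / frames$N_ll) * t_ll / e_ll, 0)
  pi <- ll_term + (config$n_cell / frames$N_cell) * t_cell
  if (any(pi <= 0)) {
    stop("respondent with no phone number in either frame", call. = FALSE)
  }
  if (any(pi > 1)) {
    stop("selection probability exceeds 1: frame counts are mis-specified",
         call. = FALSE)
  }
  pi
}

#' Counterfactual single-frame (cell-only) selection probability
#'
#' \deqn{\pi_i^{sf} = \frac{n_C}{N_C} \frac{t_C^i}{e_C^i}, \quad e_C^i = 1.}
#' Defined for cell-owning respondents only.
#'
#' @inheritParams df_selection_probability
#' @return numeric vector of selection probabilities.
#' @export
sf_selection_probability <- function(respondents, frames, config,
                                     multiplicity_cap = 3L) {
  t_cell <- pmin(respondents$t_cell, multiplicity_cap)
  if (any(t_cell < 1)) {
    stop("single-frame probability requested for a respondent with no cell number",
         call. = FALSE)
  }
  pi <- (config$n_cell / frames$N_cell) * t_cell
  if (any(pi > 1)) {
    stop("selection probability exceeds 1: frame counts are mis-specified",
         call. = FALSE)
  }
  pi
}

#' Per-respondent weights for a named design
#'
#' @param design_label "DF" or "SF".
#' @param respondent_id respondent identifiers.
#' @param weight positive finite design (or calibrated) weights.
#' @return a `weight_set` data frame with the dispersion summary attached.
#' @export
weight_set <- function(design_label, respondent_id, weight) {
  design_label <- match.arg(design_label, c("DF", "SF"))
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop("weights must be positive and finite", call. = FALSE)
  }
  structure(data.frame(respondent_id = respondent_id, weight = weight),
            design_label = design_label,
            dispersion = weight_dispersion(weight),
            class = c("weight_set", "data.frame"))
}

#' Build the counterfactual single-frame respondent set
#'
#' The "as-if" single-frame cell sample is obtained by excluding the landline
#' respondents from the dual-frame sample; the retained cell respondents are
#' reweighted by the inverse of their single-frame selection probability.
#'
#' @param respondents dual-frame respondent records with `frame_of_origin`.
#' @param frames a `frame_spec`.
#' @param config a [fieldwork_config()].
#' @param multiplicity_cap see [df_selection_probability()].
#' @return list with `respondents` (the cell subset) and `weights`
#'   (a [weight_set()] labelled "SF").
#' @export
build_counterfactual_sf <- function(respondents, frames, config,
                                    multiplicity_cap = 3L) {
  sf <- respondents[respondents$frame_of_origin == "cell", , drop = FALSE]
  if (!nrow(sf)) stop("no cell-frame respondents in the sample", call. = FALSE)
  pi <- sf_selection_probability(sf, frames, config, multiplicity_cap)
  list(respondents = sf,
       weights = weight_set("SF", sf$person_id, 1 / pi))
}

#' Weight dispersion summary
#'
#' The two dispersion statistics used to compare designs: the max/min ratio
#' and the coefficient of variation (standard deviation over mean, population
#' convention with divisor n).  Both are invariant to rescaling the weights.
#'
#' @param weights positive weights.
#' @return list with `max_min_ratio` and `cv`.
#' @export
weight_dispersion <- function(weights) {
  if (!length(weights) || any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be a nonempty positive vector", call. = FALSE)
  }
  m <- mean(weights)
  sd_pop <- sqrt(mean((weights - m)^2))
  list(max_min_ratio = max(weights) / min(weights), cv = sd_pop / m)
}

#' @export
print.weight_set <- function(x, ...) {
  d <- attr(x, "dispersion")
  cat(sprintf("%s weight set: n = %d, max/min = %.2f, CV = %.2f\n",
              attr(x, "design_label"), nrow(x), d$max_min_ratio, d$cv))
  invisible(x)
}
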