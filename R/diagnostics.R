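# Representativeness diagnostics: standardized distances and R-indicators.

#' Standardized distance between a sample share and a reference share
#'
#' For a category with reference-population share `p_a` and weighted sample
#' share `p_b`,
#' \deqn{d = 100 \, (p_B - p_A) / \sqrt{(p_A q_A + p_B q_B)/2}, \quad q = 1-p,}
#' the difference in shares scaled by the pooled binomial standard deviation,
#' in percent.  Values below 10 in absolute value are conventionally read as
#' acceptable balance.
#'
#' @param p_a reference share(s) in [0, 1].
#' @param p_b weighted sample share(s) in [0, 1].
#' @return the standardized distance(s), in percent.  When `p_a == p_b` is 0
#'   or 1 the distance is 0 by continuity; degenerate unequal pairs (both
#'   shares in {0, 1}) are an error.
#' @export
standardized_distance <- function(p_a, p_b) {
  if (any(p_a < 0 | p_a > 1 | p_b < 0 | p_b > 1)) {
    stop("shares must lie in [0, 1]", call. = FALSE)
  }
  pooled <- (p_a * (1 - p_a) + p_b * (1 - p_b)) / 2
  bad <- pooled == 0 & p_a != p_b
  if (any(bad)) {
    stop("degenerate shares (both 0 or 1) with unequal values: d undefined",
         call. = FALSE)
  }
  ifelse(pooled == 0, 0, 100 * (p_b - p_a) / sqrt(pooled))
}

#' Aggregate standardized distances
#'
#' Category distances are summed up at the variable level as the unweighted
#' mean of their absolute values over the variable's m categories
#' (`variable_distance`), and at the sample level as the unweighted mean of
#' the variable-level values (`sample_distance`).  No category-size weighting
#' is applied at either level.
#'
#' @param d category-level distances of one variable.
#' @return the variable-level distance D (>= 0).
#' @export
variable_distance <- function(d) mean(abs(d))

#' @rdname variable_distance
#' @param D variable-level distances.
#' @return `sample_distance`: the sample-level mean D.
#' @export
sample_distance <- function(D) mean(D)

#' Balance report of a weighted sample against reference margins
#'
#' Computes the weighted sample share `p_B` of every category, its
#' standardized distance to the reference share `p_A`, the variable-level
#' mean absolute distance D, and the sample-level mean D.  Category distances
#' are computed independently per category (for a two-category variable the
#' two absolute values need not be equal and both are reported).
#'
#' @param data respondent categories (one column per variable).
#' @param weights positive weights (design weights when diagnosing
#'   calibration covariates, calibrated weights for external covariates).
#' @param margins named list of [margin_table()]s covering all sample
#'   categories.
#' @param variables variables to report (default: all margins).
#' @param rounded_aggregation if `TRUE`, aggregate from category distances
#'   rounded half-up to `digits` decimals, reproducing aggregates printed in
#'   survey reports; internal default is unrounded aggregation.
#' @param digits presentation precision used when `rounded_aggregation`.
#' @return a `balance_report` list: `categories` (variable, category, `p_ref`,
#'   `p_sample`, `d`), `variables` (variable, `D`, `acceptable` flag against
#'   the 10\% threshold), and `mean_D`.
#' @export
balance_report <- function(data, weights, margins, variables = names(margins),
                           rounded_aggregation = FALSE, digits = 1) {
  cat_rows <- list()
  D <- numeric(length(variables))
  for (k in seq_along(variables)) {
    v <- variables[k]
    mt <- margins[[v]]
    if (is.null(mt)) stop(sprintf("no margin for variable '%s'", v), call. = FALSE)
    x <- as.character(data[[v]])
    extra <- setdiff(unique(x), mt$category)
    if (length(extra)) {
      stop(sprintf("category '%s' of '%s' missing from the margin", extra[1], v),
           call. = FALSE)
    }
    p_b <- weighted_shares(x, weights, mt$category)
    d <- standardized_distance(mt$share, p_b)
    cat_rows[[k]] <- data.frame(variable = v, category = mt$category,
                                p_ref = mt$share, p_sample = unname(p_b),
                                d = d, stringsAsFactors = FALSE)
    D[k] <- if (rounded_aggregation) {
      variable_distance(round_half_up(d, digits))
    } else {
      variable_distance(d)
    }
  }
  D_agg <- if (rounded_aggregation) round_half_up(D, digits) else D
  structure(list(categories = do.call(rbind, cat_rows),
                 variables = data.frame(variable = variables, D = D_agg,
                                        acceptable = D_agg < 10,
                                        stringsAsFactors = FALSE),
                 mean_D = sample_distance(D_agg)),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, digits = 1, ...) {
  cat("Balance report (standardized distances, %):\n")
  v <- x$variables
  for (i in seq_len(nrow(v))) {
    cat(sprintf("  %-14s D = %5.1f %s\n", v$variable[i],
                round_half_up(v$D[i], digits),
                if (v$acceptable[i]) "" else "(> 10: imbalance)"))
  }
  cat(sprintf("  mean D = %.1f\n", round_half_up(x$mean_D, digits)))
  invisible(x)
}

#' Model-based R-indicator of sample representativeness
#'
#' Stacks the sample on a benchmark (census-like) dataset, fits a
#' main-effects logistic model for membership of the sample rather than the
#' benchmark, and converts each predicted membership probability `m(x)` to
#' the selection-propensity scale as the odds `m/(1-m)` — which, with the
#' benchmark weighted to population counts and the sample counted once per
#' interview, estimates the sampling rate at covariate value x (capped at 1).
#' The indicator is
#' \deqn{R = 1 - 2 S(\hat\rho),}
#' where S is the benchmark-weighted standard deviation of the predicted
#' propensities over the population.  R lies in [0, 1]; R = 1 when all
#' propensities are equal (a perfectly balanced sample), and lower values
#' indicate stronger covariate-driven selection.
#'
#' @param sample_data sample covariates (data frame).
#' @param reference_data benchmark covariates (data frame with the same
#'   columns); should be large relative to the sample.
#' @param covariates covariate names entered as main effects.
#' @param sample_weights optional sample design weights; normalized to the
#'   sample size, so the indicator is invariant to rescaling them.
#' @param reference_weights optional benchmark weights (population counts).
#' @return an `r_indicator_result` list: `R`, `propensity_sd`, `model`
#'   (a one-line description), `propensities` (per benchmark unit).
#' @export
r_indicator <- function(sample_data, reference_data, covariates,
                        sample_weights = NULL, reference_weights = NULL) {
  for (v in covariates) {
    if (!v %in% names(sample_data) || !v %in% names(reference_data)) {
      stop(sprintf("covariate '%s' missing from sample or benchmark", v),
           call. = FALSE)
    }
  }
  n_s <- nrow(sample_data)
  n_r <- nrow(reference_data)
  w_s <- if (is.null(sample_weights)) rep(1, n_s) else
    sample_weights * n_s / sum(sample_weights)
  w_r <- if (is.null(reference_weights)) rep(1, n_r) else reference_weights

  lv <- lapply(covariates, function(v) {
    sort(unique(c(as.character(sample_data[[v]]), as.character(reference_data[[v]]))))
  })
  names(lv) <- covariates
  stack_cov <- function(d) {
    out <- lapply(covariates, function(v) factor(as.character(d[[v]]), lv[[v]]))
    names(out) <- covariates
    as.data.frame(out)
  }
  stacked <- rbind(stack_cov(sample_data), stack_cov(reference_data))
  stacked$.member <- c(rep(1, n_s), rep(0, n_r))
  stacked$.w <- c(w_s, w_r)

  fit <- stats::glm(stats::reformulate(covariates, ".member"),
                    family = stats::quasibinomial(), data = stacked,
                    weights = stacked$.w)
  if (!fit$converged) {
    stop("propensity model did not converge", call. = FALSE)
  }
  m <- stats::predict(fit, type = "response")
  if (any(m > 1 - 1e-10) || any(m < 1e-14)) {
    stop("perfect separation in the propensity model: coarsen the covariates",
         call. = FALSE)
  }
  # membership odds = sample mass / population mass at x = sampling rate
  rho <- pmin(m / (1 - m), 1)[stacked$.member == 0]
  mu <- sum(w_r * rho) / sum(w_r)
  s <- sqrt(sum(w_r * (rho - mu)^2) / sum(w_r))
  structure(list(R = 1 - 2 * s, propensity_sd = s,
                 mean_propensity = mu,
                 model = paste("main-effects logistic:",
                               paste(covariates, collapse = " + ")),
                 propensities = rho),
            class = "r_indicator_result")
}

#' @export
print.r_indicator_result <- function(x, ...) {
  cat(sprintf("R-indicator: %.3f (SD of propensities %.4f; %s)\n",
              x$R, x$propensity_sd, x$model))
  invisible(x)
}
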