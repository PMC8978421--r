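# Design-comparison estimation: weighted prevalences, design effects,
# relative differences, AAPOR outcome rates.

#' Weighted prevalence with linearized standard error
#'
#' The ratio (Hajek) estimator \eqn{\bar y = \sum w_i y_i / \sum w_i} with a
#' Taylor-linearized variance under a single-stage with-replacement
#' approximation, treating the weights as fixed:
#' \deqn{\widehat{var}(\bar y) = \frac{n}{n-1}
#'   \frac{\sum_i w_i^2 (y_i - \bar y)^2}{(\sum_i w_i)^2}.}
#'
#' @param y binary (0/1) responses.
#' @param weights positive weights.
#' @return list with `estimate`, `se`, `variance`, `n`.
#' @export
weighted_prevalence <- function(y, weights) {
  n <- length(y)
  if (n == 0) stop("empty input", call. = FALSE)
  if (length(weights) != n) stop("y and weights differ in length", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be positive and finite", call. = FALSE)
  }
  if (any(!y %in% c(0, 1))) stop("responses must be binary 0/1", call. = FALSE)
  ybar <- sum(weights * y) / sum(weights)
  v <- if (n > 1) {
    n / (n - 1) * sum((weights * (y - ybar))^2) / sum(weights)^2
  } else NA_real_
  list(estimate = ybar, se = sqrt(v), variance = v, n = n)
}

#' Design effect factor (deft)
#'
#' \deqn{deft = \sqrt{var(\bar y) / (s^2/n)},} the ratio of the design-based
#' standard error to the standard error of a simple random sample of the same
#' size, with \eqn{s^2 = p(1-p)} for a binary variable of proportion p.
#' A deft of 1 means the design is as precise as simple random sampling.
#'
#' @param ybar weighted prevalence in (0, 1).
#' @param var_ybar design-based variance of the prevalence.
#' @param n sample size (>= 2).
#' @return the deft value.
#' @export
deft <- function(ybar, var_ybar, n) {
  if (any(ybar <= 0 | ybar >= 1)) {
    stop("deft undefined for a degenerate proportion", call. = FALSE)
  }
  if (any(var_ybar < 0) || any(n < 2)) {
    stop("need var_ybar >= 0 and n >= 2", call. = FALSE)
  }
  sqrt(var_ybar / (ybar * (1 - ybar) / n))
}

#' Relative difference between single-frame and dual-frame estimates
#'
#' \deqn{100 \, (\bar y_{sf} - \bar y_{df}) / \bar y_{df}} in percent.
#'
#' @param ybar_sf,ybar_df prevalence estimates; `ybar_df` must be > 0.
#' @return the relative difference in percent.
#' @export
relative_difference <- function(ybar_sf, ybar_df) {
  if (any(ybar_df <= 0)) {
    stop("relative difference undefined for a zero dual-frame estimate",
         call. = FALSE)
  }
  100 * (ybar_sf - ybar_df) / ybar_df
}

#' AAPOR response rate 3
#'
#' \deqn{RR3 = \frac{I}{I + P + R + NC + O + e (UH + UO)},}
#' where I are complete interviews, P partials, R refusals, NC non-contacts,
#' O other eligible non-interviews, UH/UO unknown-eligibility cases, and e
#' the estimated eligibility fraction of the unknowns.  By default e is the
#' proportional (CASRO) allocation among resolved numbers:
#' `e = (I+P+R+NC+O) / (I+P+R+NC+O+NE)`, with NE the known-ineligible
#' (e.g. non-working) numbers.
#'
#' @param counts named vector or one-frame disposition data frame (columns
#'   `code`, `count`) holding I, P, R, NC, O, UH, UO, NE.
#' @param e eligibility fraction for unknowns in [0, 1]; `NULL` (default)
#'   uses the proportional allocation.
#' @return list with `rr3` and `e`.
#' @export
aapor_rr3 <- function(counts, e = NULL) {
  if (is.data.frame(counts)) {
    counts <- stats::setNames(counts$count, counts$code)
  }
  g <- function(code) if (code %in% names(counts)) as.numeric(counts[[code]]) else 0
  if (any(unlist(lapply(DISPOSITION_CODES, g)) < 0)) {
    stop("disposition counts must be non-negative", call. = FALSE)
  }
  eligible <- g("I") + g("P") + g("R") + g("NC") + g("O")
  if (is.null(e)) {
    resolved <- eligible + g("NE")
    if (resolved == 0) stop("no resolved numbers to estimate e", call. = FALSE)
    e <- eligible / resolved
  }
  if (e < 0 || e > 1) stop("e must lie in [0, 1]", call. = FALSE)
  denom <- eligible + e * (g("UH") + g("UO"))
  if (denom == 0) stop("zero denominator in RR3", call. = FALSE)
  list(rr3 = g("I") / denom, e = e)
}

#' AAPOR outcome rates per frame and overall
#'
#' @param dispositions disposition table from [simulate_calls()] (columns
#'   `frame`, `code`, `count`).
#' @param e optional fixed eligibility fraction; default proportional per
#'   frame (and pooled for the overall rate).
#' @return data frame with columns `frame`, `rr3`, `e`.
#' @export
outcome_rates <- function(dispositions, e = NULL) {
  one <- function(d) aapor_rr3(stats::setNames(d$count, d$code), e)
  frames <- unique(dispositions$frame)
  rows <- lapply(frames, function(f) {
    r <- one(dispositions[dispositions$frame == f, ])
    data.frame(frame = f, rr3 = r$rr3, e = r$e)
  })
  pooled <- aggregate(count ~ code, dispositions, sum)
  r <- aapor_rr3(stats::setNames(pooled$count, pooled$code), e)
  do.call(rbind, c(rows, list(data.frame(frame = "overall", rr3 = r$rr3, e = r$e))))
}

#' Compare dual-frame and single-frame estimates
#'
#' Produces the design-comparison report: per indicator and population scope
#' (overall and age subgroups), the weighted prevalence, its linearized SE,
#' the deft, and the relative difference of the single-frame estimate to the
#' dual-frame estimate.  Subgroup estimates reuse the full-sample weights
#' (no re-calibration within subgroup).
#'
#' @param df_respondents,sf_respondents respondent records of the two
#'   designs, carrying the indicator columns and `age`.
#' @param df_weights,sf_weights weight vectors aligned with the respondent
#'   rows (typically calibrated weights).
#' @param indicators indicator column names (default the seven health
#'   indicators of the generator).
#' @param subgroups named list of age ranges `c(lower, upper)`; `NULL` entries
#'   mean the whole sample.  Default: overall, 18-30, 60-75.
#' @return an `estimate_report` data frame with one row per scope x indicator.
#' @export
compare_designs <- function(df_respondents, df_weights,
                            sf_respondents, sf_weights,
                            indicators = HEALTH_INDICATORS,
                            subgroups = list(all = NULL,
                                             "18-30" = c(18, 30),
                                             "60-75" = c(60, 75))) {
  miss <- setdiff(indicators, intersect(names(df_respondents), names(sf_respondents)))
  if (length(miss)) {
    stop(sprintf("indicator '%s' missing from a design", miss[1]), call. = FALSE)
  }
  rows <- list()
  for (sg in names(subgroups)) {
    rng <- subgroups[[sg]]
    in_df <- if (is.null(rng)) rep(TRUE, nrow(df_respondents)) else
      df_respondents$age >= rng[1] & df_respondents$age <= rng[2]
    in_sf <- if (is.null(rng)) rep(TRUE, nrow(sf_respondents)) else
      sf_respondents$age >= rng[1] & sf_respondents$age <= rng[2]
    for (ind in indicators) {
      est_df <- weighted_prevalence(df_respondents[[ind]][in_df], df_weights[in_df])
      est_sf <- weighted_prevalence(sf_respondents[[ind]][in_sf], sf_weights[in_sf])
      # degenerate subgroup estimates (0 or 1) leave deft/relative difference NA
      safe_deft <- function(e) if (e$estimate > 0 && e$estimate < 1 && e$n >= 2)
        deft(e$estimate, e$variance, e$n) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        scope = sg, indicator = ind,
        n_df = est_df$n, prev_df = est_df$estimate, se_df = est_df$se,
        deft_df = safe_deft(est_df),
        n_sf = est_sf$n, prev_sf = est_sf$estimate, se_sf = est_sf$se,
        deft_sf = safe_deft(est_sf),
        relative_difference = if (est_df$estimate > 0)
          relative_difference(est_sf$estimate, est_df$estimate) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), class = c("estimate_report", "data.frame"))
}

#' @export
print.estimate_report <- function(x, ...) {
  cat("Design comparison (prevalence % (SE), deft, relative difference %):\n")
  for (sg in unique(x$scope)) {
    cat(sprintf("-- %s --\n", sg))
    sub <- x[x$scope == sg, ]
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("  %-22s DF %5.1f (%.1f) deft %.2f | SF %5.1f (%.1f) deft %.2f | rel diff %+6.1f\n",
                  sub$indicator[i],
                  100 * sub$prev_df[i], 100 * sub$se_df[i], sub$deft_df[i],
                  100 * sub$prev_sf[i], 100 * sub$se_sf[i], sub$deft_sf[i],
                  sub$relative_difference[i]))
    }
  }
  invisible(x)
}
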