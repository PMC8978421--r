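# Raking-ratio calibration (iterative proportional fitting on weights).

#' Calibrate weights to reference margins by the raking ratio
#'
#' Cyclically multiplies the weights, one margin variable at a time, by the
#' ratio of the target category total to the current weighted category total,
#' until every margin is reproduced within tolerance.  Margins are shares
#' scaled to `population_total`, so converged weights sum to the population
#' size; relative weights within each cell of the full cross-classification
#' are preserved.
#'
#' @param weights positive starting (design) weights.
#' @param data data frame of respondent categories, one column per margin
#'   variable.
#' @param margins named list of [margin_table()]s (names = variables in
#'   `data`).
#' @param population_total reference population size the margins are scaled
#'   to (default 1: weights sum to 1 at convergence).
#' @param tol stopping rule: maximum relative margin deviation (default 1e-8).
#' @param max_cycles maximum full cycles over the margin variables.
#' @return a `raking_result` list: `weights`, `iterations` (cycles used),
#'   `max_deviation` at exit, `converged` flag.
#' @export
rake <- function(weights, data, margins, population_total = 1,
                 tol = 1e-8, max_cycles = 100L) {
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("starting weights must be positive", call. = FALSE)
  }
  vars <- names(margins)
  if (is.null(vars) || any(!vars %in% names(data))) {
    stop("every margin variable must be a column of `data`", call. = FALSE)
  }
  # structural zeros: a target category with positive share but no sample unit
  fac <- list()
  for (v in vars) {
    mt <- margins[[v]]
    f <- factor(as.character(data[[v]]), levels = mt$category)
    if (anyNA(f)) {
      bad <- unique(as.character(data[[v]])[is.na(f)])
      stop(sprintf("category '%s' of '%s' present in sample but absent from margin",
                   bad[1], v), call. = FALSE)
    }
    empty <- mt$category[mt$share > 0 & !(mt$category %in% f)]
    if (length(empty)) {
      stop(sprintf("structural zero: no sample unit in category '%s' of '%s'",
                   empty[1], v), call. = FALSE)
    }
    fac[[v]] <- f
  }

  w <- weights * (population_total / sum(weights))
  iterations <- 0L
  dev <- margin_deviation(w, data, margins)
  while (dev > tol && iterations < max_cycles) {
    for (v in vars) {
      target <- margins[[v]]$share * population_total
      current <- as.vector(tapply(w, fac[[v]], sum, default = 0))
      ratio <- ifelse(current > 0, target / current, 1)
      w <- w * ratio[as.integer(fac[[v]])]
    }
    iterations <- iterations + 1L
    dev <- margin_deviation(w, data, margins)
  }

  structure(list(weights = w, iterations = iterations,
                 max_deviation = dev, converged = dev <= tol),
            class = "raking_result")
}

#' Maximum relative margin deviation of weighted shares
#'
#' `max over categories of |weighted share - target share| / target share`,
#' over all margin variables.  A category with target share 0 but positive
#' weighted share yields `Inf`.
#'
#' @inheritParams rake
#' @return the maximum relative deviation (scale-invariant in the weights).
#' @export
margin_deviation <- function(weights, data, margins) {
  dev <- 0
  for (v in names(margins)) {
    mt <- margins[[v]]
    ws <- weighted_shares(as.character(data[[v]]), weights, mt$category)
    d <- ifelse(mt$share > 0, abs(ws - mt$share) / mt$share,
                ifelse(ws > 0, Inf, 0))
    dev <- max(dev, d)
  }
  dev
}

#' @export
print.raking_result <- function(x, ...) {
  cat(sprintf("Raking: %s after %d cycles (max relative margin deviation %.2e)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$max_deviation))
  invisible(x)
}
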