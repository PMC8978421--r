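#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, the convention used in
#' printed survey reports (base `round()` rounds ties to even, so e.g.
#' `round(10.25, 1)` gives 10.2 where a report prints 10.3).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, ties away from zero.
#' @examples
#' round_half_up(10.25, 1)  # 10.3
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Validate that a share vector is a proper probability distribution.
check_shares <- function(shares, what, tol = 1e-9) {
  if (any(!is.finite(shares)) || any(shares < 0)) {
    stop(sprintf("invalid %s shares: must be finite and non-negative", what),
         call. = FALSE)
  }
  if (abs(sum(shares) - 1) > tol) {
    stop(sprintf("%s shares sum to %.10f, not 1", what, sum(shares)),
         call. = FALSE)
  }
  invisible(shares)
}

# Weighted share of each level of a factor; levels with no mass get 0.
weighted_shares <- function(x, w, levels) {
  tot <- vapply(levels, function(lv) sum(w[x == lv]), numeric(1))
  tot / sum(w)
}

# Derive a child seed from a master seed and a stream label, kept inside the
# 32-bit integer range so set.seed() accepts it.
child_seed <- function(seed, stream) {
  offsets <- c(population = 11L, fieldwork = 23L, calibration = 37L,
               estimation = 41L, replicate = 53L)
  off <- if (is.character(stream)) offsets[[stream]] else as.integer(stream)
  as.integer((as.double(seed) * 1009 + off) %% 2147483629)
}
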