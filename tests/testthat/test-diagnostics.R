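test_that("standardized distance matches hand arithmetic and its symmetries", {
  expect_equal(standardized_distance(0.3, 0.3), 0)
  expect_equal(standardized_distance(0.5, 0.6),
               100 * 0.1 / sqrt((0.25 + 0.24) / 2))
  # antisymmetry and sign convention on a grid
  grid <- expand.grid(a = seq(0.05, 0.95, 0.15), b = seq(0.05, 0.95, 0.15))
  d <- standardized_distance(grid$a, grid$b)
  expect_equal(d, -standardized_distance(grid$b, grid$a))
  expect_equal(sign(d), sign(grid$b - grid$a))
  expect_equal(d == 0, grid$a == grid$b)
  # continuity at shared degenerate shares; error when both degenerate unequal
  expect_equal(standardized_distance(0, 0), 0)
  expect_equal(standardized_distance(1, 1), 0)
  expect_error(standardized_distance(0, 1), "degenerate")
  expect_error(standardized_distance(0.5, 1.2), "\\[0, 1\\]")
})

test_that("aggregation is a two-level unweighted mean of absolute values", {
  expect_equal(variable_distance(c(-2.3, 0.5, -2.3, -1.5, 2.6, 2.7)), 11.9 / 6)
  expect_equal(sample_distance(c(5.6, 2.0, 10.3, 7.4, 2.6, 1.7)), 29.6 / 6)
})

test_that("balance_report computes weighted shares, d, D and mean D", {
  data <- data.frame(g = rep(c("a", "b"), c(30, 70)),
                     h = rep(c("x", "y"), 50))
  w <- rep(1, 100)
  margins <- list(g = margin_table("g", c("a", "b"), c(0.5, 0.5)),
                  h = margin_table("h", c("x", "y"), c(0.5, 0.5)))
  br <- balance_report(data, w, margins)
  expect_equal(br$categories$p_sample, c(0.3, 0.7, 0.5, 0.5))
  d_a <- standardized_distance(0.5, 0.3)
  expect_equal(br$variables$D, c(abs(d_a), 0))
  expect_equal(br$mean_D, abs(d_a) / 2)
  # two-category variables report both category values independently
  expect_equal(nrow(br$categories[br$categories$variable == "g", ]), 2)

  # sample equal to the reference: all distances vanish
  br0 <- balance_report(data.frame(g = rep(c("a", "b"), 50)), w,
                        list(g = margin_table("g", c("a", "b"), c(0.5, 0.5))))
  expect_equal(br0$mean_D, 0)
  expect_error(balance_report(data.frame(g = "zz"), 1, margins["g"]),
               "'zz'")
})

test_that("rounded aggregation reproduces report-style values", {
  data <- data.frame(g = rep(c("a", "b"), c(30, 70)))
  margins <- list(g = margin_table("g", c("a", "b"), c(0.5, 0.5)))
  br <- balance_report(data, rep(1, 100), margins, rounded_aggregation = TRUE)
  d_rounded <- round_half_up(standardized_distance(0.5, 0.3), 1)
  expect_equal(br$variables$D, round_half_up(abs(d_rounded), 1))
})

test_that("R-indicator equals the closed form on a saturated two-stratum design", {
  ref <- data.frame(g = rep(c("s1", "s2"), each = 5000))
  # sampling rates 0.15 and 0.05 (ratio 3:1) over equal strata
  smp <- data.frame(g = rep(c("s1", "s2"), c(750, 250)))
  r <- r_indicator(smp, ref, "g")
  expect_equal(sort(unique(round(r$propensities, 10))), c(0.05, 0.15))
  expect_equal(r$R, 1 - 2 * 0.05, tolerance = 1e-6)
  expect_equal(r$propensity_sd, 0.05, tolerance = 1e-6)

  # an exact proportional subsample is perfectly balanced
  smp_prop <- data.frame(g = rep(c("s1", "s2"), c(500, 500)))
  expect_equal(r_indicator(smp_prop, ref, "g")$R, 1, tolerance = 1e-6)

  # invariance to rescaling design weights
  r_w <- r_indicator(smp, ref, "g", sample_weights = rep(2, 1000))
  r_w2 <- r_indicator(smp, ref, "g", sample_weights = rep(9000, 1000))
  expect_equal(r_w$R, r_w2$R)
  expect_equal(r_w$R, r$R, tolerance = 1e-6)
})

test_that("R decreases as stratum sampling rates grow more heterogeneous", {
  ref <- data.frame(g = rep(c("s1", "s2"), each = 5000))
  splits <- list(c(550, 450), c(650, 350), c(800, 200), c(950, 50))
  R <- vapply(splits, function(s) {
    r_indicator(data.frame(g = rep(c("s1", "s2"), s)), ref, "g")$R
  }, numeric(1))
  expect_true(all(diff(R) < 0))
  expect_true(all(R >= 0 & R <= 1))
})

test_that("R-indicator is within bounds on the study scenario and errors are caught", {
  ex <- study_experiment()
  for (d in c("DF", "SF")) {
    expect_gte(ex$r_indicators[[d]]$R, 0)
    expect_lte(ex$r_indicators[[d]]$R, 1)
  }
  expect_error(r_indicator(data.frame(g = "a"), data.frame(h = "b"), "g"),
               "missing")
})
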