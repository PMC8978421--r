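test_that("weighted prevalence is the ratio estimator", {
  expect_equal(weighted_prevalence(c(1, 0, 1, 0), rep(1, 4))$estimate, 0.5)
  expect_equal(weighted_prevalence(c(1, 0), c(3, 1))$estimate, 0.75)
  expect_error(weighted_prevalence(numeric(0), numeric(0)), "empty")
  expect_error(weighted_prevalence(c(1, 2), c(1, 1)), "binary")
  expect_error(weighted_prevalence(c(1, 0), c(1, -1)), "positive")
  # scale invariance
  e1 <- weighted_prevalence(c(1, 0, 0, 1, 1), 1:5)
  e2 <- weighted_prevalence(c(1, 0, 0, 1, 1), (1:5) * 100)
  expect_equal(e1$estimate, e2$estimate)
  expect_equal(e1$se, e2$se)
})

test_that("linearized SE agrees with a bootstrap oracle", {
  set.seed(101)
  n <- 150
  w <- exp(rnorm(n, 0, 0.6))
  y <- rbinom(n, 1, 0.3)
  est <- weighted_prevalence(y, w)
  boot <- replicate(2000, {
    i <- sample.int(n, n, replace = TRUE)
    sum(w[i] * y[i]) / sum(w[i])
  })
  expect_lt(abs(est$se - sd(boot)) / sd(boot), 0.10)
})

test_that("deft follows its definition and the SRS limit", {
  p <- 0.2; n <- 500
  expect_equal(deft(p, p * (1 - p) / n, n), 1)
  expect_equal(deft(p, 4 * p * (1 - p) / n, n), 2)
  expect_error(deft(0, 0.001, 100), "degenerate")
  expect_error(deft(0.5, -1, 100), "var_ybar")

  # equal-weight simple random samples from the synthetic population: deft ~ 1
  pop <- small_world()$population
  set.seed(55)
  defts <- replicate(300, {
    idx <- sample.int(nrow(pop$persons), 400)
    est <- weighted_prevalence(pop$persons$daily_smoking[idx], rep(1, 400))
    deft(est$estimate, est$variance, est$n)
  })
  expect_lt(abs(mean(defts) - 1), 0.01)
})

test_that("relative difference matches the printed convention", {
  expect_equal(relative_difference(5.7, 6.0), -5)
  expect_equal(round_half_up(relative_difference(36.3, 36.6), 1), -0.8)
  expect_equal(relative_difference(0.4, 0.4), 0)
  expect_error(relative_difference(1, 0), "zero")
  # scale invariance: proportions or percents give the same answer
  expect_equal(relative_difference(0.057, 0.060), relative_difference(5.7, 6.0))
})

test_that("AAPOR RR3 matches hand-computed values", {
  expect_equal(aapor_rr3(c(I = 35, P = 0, R = 40, NC = 25, O = 0))$rr3, 0.35)
  # all unknowns, e = 0: unknowns drop from the denominator
  expect_equal(aapor_rr3(c(I = 10, R = 10, UH = 100), e = 0)$rr3, 0.5)
  # proportional e: e = 100 / 150 = 2/3; denominator 100 + (2/3)*30 = 120
  r <- aapor_rr3(c(I = 50, P = 5, R = 30, NC = 15, NE = 50, UH = 20, UO = 10))
  expect_equal(r$e, 2 / 3)
  expect_equal(r$rr3, 50 / 120)
  expect_error(aapor_rr3(c(I = -1)), "non-negative")
  expect_error(aapor_rr3(c(UH = 10)), "no resolved")

  rates <- outcome_rates(data.frame(frame = rep(c("landline", "cell"), each = 2),
                                    code = c("I", "NE", "I", "R"),
                                    count = c(30, 30, 40, 40)))
  expect_equal(rates$rr3[rates$frame == "landline"], 1)
  expect_equal(rates$rr3[rates$frame == "cell"], 0.5)
  expect_equal(rates$rr3[rates$frame == "overall"], 70 / 110)
})

test_that("compare_designs builds the full report and degenerates correctly", {
  set.seed(9)
  n <- 400
  resp <- data.frame(age = sample(18:75, n, TRUE),
                     smoking = rbinom(n, 1, 0.3),
                     obesity = rbinom(n, 1, 0.15))
  w <- runif(n, 0.5, 2)
  rep_same <- compare_designs(resp, w, resp, w,
                              indicators = c("smoking", "obesity"))
  expect_equal(nrow(rep_same), 2 * 3)
  expect_true(all(rep_same$relative_difference == 0))
  expect_equal(rep_same$prev_df, rep_same$prev_sf)
  expect_error(compare_designs(resp, w, resp["age"], w, indicators = "smoking"),
               "missing")
})

test_that("study scenario: SF deft below DF deft, report structurally complete", {
  ex <- study_experiment()
  est <- as.data.frame(ex$estimates)
  expect_equal(nrow(est), 7 * 3)
  expect_setequal(unique(est$scope), c("all", "18-30", "60-75"))
  ov <- est[est$scope == "all", ]
  expect_true(all(ov$deft_sf < ov$deft_df))
  expect_true(all(est$prev_df >= 0 & est$prev_df <= 1))
  expect_true(all(est$se_df > 0 & est$se_sf > 0))
})
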