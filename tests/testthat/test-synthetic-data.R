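test_that("degenerate equipment models are honoured exactly", {
  bands <- names(population_config()$equipment_model$cell_age)
  cfg <- population_config(
    population_size = 2000,
    equipment_model = list(cell_age = setNames(rep(1, 6), bands),
                           landline_age = setNames(rep(0, 6), bands)),
    seed = 3)
  pop <- generate_population(cfg)
  expect_true(all(pop$persons$n_cell >= 1))
  expect_true(all(pop$persons$n_landline == 0))
  expect_true(all(pop$persons$equipment == "cell_only"))
})

test_that("realized cell ownership matches the model-implied marginal", {
  cfg <- population_config(population_size = 100000, seed = 1)
  pop <- generate_population(cfg)
  p <- implied_equipment_rates(cfg)$cell
  realized <- mean(pop$persons$n_cell > 0)
  se <- sqrt(p * (1 - p) / cfg$population_size)
  expect_lt(abs(realized - p), 3 * se)
  # overall coverage close to the published French rates (96% cell, 77% landline)
  expect_lt(abs(realized - 0.96), 0.02)
  expect_lt(abs(mean(pop$persons$n_landline > 0) - 0.77), 0.03)
  # gradient direction: cell ownership decreases with age, landline increases
  by_age <- tapply(pop$persons$n_cell > 0, pop$persons$age_band, mean)
  expect_gt(by_age[["18-24"]], by_age[["65-75"]])
  ll_by_age <- tapply(pop$persons$n_landline > 0, pop$persons$age_band, mean)
  expect_lt(ll_by_age[["18-24"]], ll_by_age[["65-75"]])

  # every realized categorical share within 4 binomial SEs of its target
  sh <- cfg$category_shares
  for (v in c("education", "hh_size", "urbanization", "region")) {
    realized <- as.vector(table(factor(pop$persons[[v]], names(sh[[v]])))) /
      cfg$population_size
    bound <- 4 * sqrt(sh[[v]] * (1 - sh[[v]]) / cfg$population_size)
    expect_true(all(abs(realized - sh[[v]]) < bound), label = v)
  }
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- population_config(population_size = 3000, seed = 5)
  expect_identical(generate_population(cfg), generate_population(cfg))
})

test_that("households conserve persons and equipment classes partition", {
  pop <- small_world()$population
  p <- pop$persons
  expect_equal(sum(pop$households$size), nrow(p))
  expect_equal(sort(unique(p$household_id)), pop$households$household_id)
  expect_equal(as.vector(table(p$household_id)), pop$households$size)
  expect_true(all(p$equipment %in% c("phoneless", "landline_only",
                                     "cell_only", "both")))
  expect_equal(p$equipment == "both" | p$equipment == "cell_only", p$n_cell > 0)
  expect_true(all(p$e_ll >= 1))
  # landline counts are a household attribute shared by all members
  expect_true(all(tapply(p$n_landline, p$household_id,
                         function(x) length(unique(x))) == 1))
})

test_that("frame sizes follow the non-working-rate arithmetic", {
  pop <- small_world()$population
  w_ll <- sum(pop$households$n_landline[pop$households$owns_landline])
  w_c <- sum(pop$persons$n_cell)

  fr <- build_frames(pop, 0.5, 0.33)
  expect_equal(fr$N_ll, round(w_ll / 0.5))
  expect_equal(fr$N_cell, round(w_c / 0.67))
  expect_equal(sum(fr$ll$working), w_ll)
  expect_equal(sum(fr$cell$working), w_c)

  fr0 <- build_frames(pop, 0, 0)
  expect_equal(fr0$N_ll, w_ll)
  expect_equal(fr0$N_cell, w_c)
  expect_true(all(fr0$cell$working))

  expect_error(build_frames(pop, 1, 0.33), "non-working rate")
  # every working number is attached to an owner
  expect_false(anyNA(fr$ll$owner_id[fr$ll$working]))
  expect_true(all(is.na(fr$ll$owner_id[!fr$ll$working])))
})

test_that("reference margins are exact population frequencies", {
  persons <- data.frame(person_id = 1:10,
                        sex = rep(c("male", "female"), each = 5))
  m <- reference_margins(fake_population(persons), "sex")$sex
  expect_equal(m$share, c(0.5, 0.5))
  expect_equal(m$category, c("male", "female"))

  pop <- small_world()$population
  margins <- reference_margins(pop)
  for (mt in margins) expect_equal(sum(mt$share), 1)
  expect_error(reference_margins(pop, "shoe_size"), "unknown")

  # margins of a large generated population track the configured shares
  cfg <- population_config(population_size = 100000, seed = 1)
  big <- generate_population(cfg)
  m <- reference_margins(big, "education")$education
  bound <- 4 * sqrt(cfg$category_shares$education *
                      (1 - cfg$category_shares$education) / 1e5)
  expect_true(all(abs(m$share - cfg$category_shares$education) < bound))
})

test_that("invalid configurations are rejected", {
  expect_error(population_config(population_size = 0), "positive")
  expect_error(population_config(category_shares = list(sex = c(male = -0.2, female = 1.2))),
               "invalid")
  expect_error(margin_table("sex", c("a", "a"), c(0.5, 0.5)), "unique")
  expect_error(margin_table("sex", c("a", "b"), c(0.5, 0.6)), "sum")
})
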