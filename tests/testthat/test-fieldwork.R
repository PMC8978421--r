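test_that("number draws are SRSWOR with the right inclusion rates", {
  w <- small_world()
  cfg <- fieldwork_config(n_ll = 10, n_cell = w$frames$N_cell, seed = 2)
  set.seed(1)
  d <- draw_numbers(w$frames, cfg)
  expect_equal(d$cell, seq_len(w$frames$N_cell))  # exhaustive draw
  expect_equal(length(d$ll), 10)
  expect_true(all(d$ll %in% seq_len(w$frames$N_ll)))

  set.seed(42); d1 <- draw_numbers(w$frames, cfg)
  set.seed(42); d2 <- draw_numbers(w$frames, cfg)
  expect_identical(d1, d2)

  expect_error(draw_numbers(w$frames, fieldwork_config(n_ll = w$frames$N_ll + 1,
                                                       n_cell = 1)),
               "exceeds frame size")

  # Monte-Carlo inclusion frequency of one number approaches n/N
  fr <- fake_frames(N_ll = 20, N_cell = 20)
  cfg <- fieldwork_config(n_ll = 5, n_cell = 5)
  set.seed(99)
  hits <- replicate(2000, 7 %in% draw_numbers(fr, cfg)$ll)
  p <- 5 / 20
  expect_lt(abs(mean(hits) - p), 4 * sqrt(p * (1 - p) / 2000))
})

test_that("Kish selection is uniform over eligibles", {
  expect_equal(kish_select(42L), 42L)
  expect_error(kish_select(integer(0)), "ineligible")
  set.seed(8)
  picks <- replicate(4000, kish_select(c(1L, 2L)))
  expect_lt(abs(mean(picks == 1L) - 0.5), 4 * sqrt(0.25 / 4000))
})

test_that("full response turns every dialed working cell number into a complete", {
  w <- small_world()
  frames0 <- build_frames(w$population, 0, 0)  # no non-working numbers
  cfg <- fieldwork_config(n_ll = 50, n_cell = 200, seed = 3)
  set.seed(3)
  res <- simulate_calls(draw_numbers(frames0, cfg), w$population, frames0, cfg,
                        full_response = TRUE)
  d <- res$dispositions
  expect_equal(d$count[d$frame == "cell" & d$code == "I"], 200)
  expect_equal(d$count[d$frame == "landline" & d$code == "I"], 50)
  expect_equal(sum(d$count), 250)
})

test_that("zero contact propensity yields only non-contacts among working numbers", {
  bands <- names(population_config()$equipment_model$cell_age)
  cfg_pop <- population_config(
    population_size = 1500,
    response_model = list(contact_cell = setNames(rep(0, 6), bands),
                          contact_landline = setNames(rep(0, 6), bands),
                          unknown_frac = 0),
    seed = 4)
  pop <- generate_population(cfg_pop)
  frames <- build_frames(pop)
  cfg <- fieldwork_config(n_ll = 100, n_cell = 200, seed = 4)
  set.seed(4)
  res <- simulate_calls(draw_numbers(frames, cfg), pop, frames, cfg)
  d <- res$dispositions
  expect_equal(sum(d$count[d$code == "I"]), 0)
  expect_equal(sum(d$count[d$code %in% c("NC", "NE")]), 300)
})

test_that("reported multiplicities equal true counts unless misreport noise is on", {
  w <- small_world()
  cfg <- fieldwork_config(n_ll = 150, n_cell = 300, seed = 6)
  set.seed(6)
  res <- simulate_calls(draw_numbers(w$frames, cfg), w$population, w$frames, cfg)
  expect_equal(res$respondents$t_cell, res$respondents$n_cell)
  expect_equal(res$respondents$t_ll, res$respondents$n_landline)

  noisy_pop <- w$population
  noisy_pop$config$misreport_prob <- 0.3
  set.seed(6)
  res2 <- simulate_calls(draw_numbers(w$frames, cfg), noisy_pop, w$frames, cfg)
  expect_gt(sum(res2$respondents$t_cell != res2$respondents$n_cell), 0)
  # reported counts stay usable: >= 1 in the frame of origin
  cell <- res2$respondents$frame_of_origin == "cell"
  expect_true(all(res2$respondents$t_cell[cell] >= 1))
  expect_true(all(res2$respondents$t_ll[!cell] >= 1))
})

test_that("dispositions partition dialed numbers and respondents own origin numbers", {
  ex <- study_experiment()
  d <- ex$fieldwork$dispositions
  expect_equal(sum(d$count[d$frame == "landline"]), ex$config$fieldwork$n_ll)
  expect_equal(sum(d$count[d$frame == "cell"]), ex$config$fieldwork$n_cell)
  expect_true(all(d$count >= 0))

  r <- ex$respondents
  expect_true(all(r$t_cell[r$frame_of_origin == "cell"] >= 1))
  expect_true(all(r$t_ll[r$frame_of_origin == "landline"] >= 1))
  expect_true(all(r$person_id %in% seq_len(ex$population_size)))
})

test_that("the landline route consumes more numbers per complete than the cell route", {
  ex <- study_experiment()
  d <- ex$fieldwork$dispositions
  dialed <- tapply(d$count, d$frame, sum)
  completes <- with(d[d$code == "I", ], setNames(count, frame))
  expect_gt(dialed[["landline"]] / completes[["landline"]],
            dialed[["cell"]] / completes[["cell"]])
  # a sizeable share of landline interviews is not with the answerer
  expect_gt(ex$fieldwork$kish_mismatch_rate, 0.1)
})
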