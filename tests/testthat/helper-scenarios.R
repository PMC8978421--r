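# Shared fixtures, built once per test run.

.scenario_cache <- new.env(parent = emptyenv())

# Reference study scenario (scaled-down national survey); expensive, so cached.
study_experiment <- function() {
  if (is.null(.scenario_cache$study)) {
    .scenario_cache$study <- run_experiment(study_config(seed = 1))
  }
  .scenario_cache$study
}

# Small population + frames reused by design-based simulation tests.
small_world <- function() {
  if (is.null(.scenario_cache$small)) {
    pop <- generate_population(population_config(population_size = 3000, seed = 11))
    .scenario_cache$small <- list(population = pop, frames = build_frames(pop))
  }
  .scenario_cache$small
}

# Hand-built stand-ins for selection-probability arithmetic.
fake_frames <- function(N_ll, N_cell) {
  structure(list(N_ll = N_ll, N_cell = N_cell), class = "frame_spec")
}
fake_fieldwork <- function(n_ll, n_cell) {
  structure(list(n_ll = n_ll, n_cell = n_cell, max_call_attempts = 5L,
                 seed = 1L),
            class = "fieldwork_config")
}

# Minimal synthetic_population wrapper around a persons table.
fake_population <- function(persons) {
  structure(list(persons = persons,
                 households = data.frame(household_id = integer()),
                 config = population_config(population_size = nrow(persons))),
            class = "synthetic_population")
}

# Independent brute-force IPF oracle on a two-way count table: alternately
# scales rows and columns to the target margins until machine convergence.
ipf_table_oracle <- function(counts, row_targets, col_targets, tol = 1e-12) {
  m <- counts / sum(counts)
  for (i in 1:10000) {
    m <- m * (row_targets / rowSums(m))
    m <- sweep(m, 2, col_targets / colSums(m), "*")
    if (max(abs(rowSums(m) - row_targets), abs(colSums(m) - col_targets)) < tol)
      break
  }
  m
}
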