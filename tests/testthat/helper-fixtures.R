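# Small worked datasets used across test files.

# 4 subjects: primary event at 1, censored at 2, competing at 3, censored at 4
four_record_data <- function() {
  cr_data(data.frame(id = 1:4, time = c(1, 2, 3, 4), status = c(1, 0, 2, 0)))
}

# 3 subjects, no censoring: primary, competing, primary
three_record_data <- function() {
  cr_data(data.frame(id = 1:3, time = c(1, 2, 3), status = c(1, 2, 1)))
}

# 4 subjects: primary, competing, censored, primary
mixed_record_data <- function() {
  cr_data(data.frame(id = 1:4, time = c(1, 2, 3, 4), status = c(1, 2, 0, 1)))
}

quiet_fine_gray <- function(...) {
  suppressWarnings(fine_gray(...))
}

# Memoised reduced-scale study cells shared between property and acceptance
# tests, so a scenario is simulated once per test run.
.study_cache <- new.env(parent = emptyenv())

cached <- function(key, fun) {
  if (!exists(key, envir = .study_cache)) {
    assign(key, fun(), envir = .study_cache)
  }
  get(key, envir = .study_cache)
}

run_cells <- function(study, grid, replicates = 100, master_seed = 7,
                      superpop_n = 100000, knot_values = NULL,
                      time_labels = NULL) {
  spec <- study_spec(study, replicates = replicates,
                     master_seed = master_seed, superpop_n = superpop_n,
                     grid = grid, knot_values = knot_values,
                     time_labels = time_labels)
  run_study(spec)
}

correct_cell_n2000 <- function() {
  cached("correct_n2000", function() {
    g <- subset(study_grid("correct_no_censoring"),
                sample_n == 2000 & beta1 == 1 & p == 0.5)
    run_cells("correct_no_censoring", g)
  })
}

quadratic_cell_n2000 <- function() {
  cached("quadratic_n2000", function() {
    g <- subset(study_grid("quadratic"),
                sample_n == 2000 & beta1 == 1 & p == 0.5)
    run_cells("quadratic", g)
  })
}

correct_cell_n1000_b05 <- function() {
  cached("correct_n1000_b05", function() {
    g <- subset(study_grid("correct_no_censoring"),
                sample_n == 1000 & beta1 == 0.5 & p == 0.5)
    run_cells("correct_no_censoring", g, time_labels = "t50")
  })
}
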