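# shared fixtures, built in code

# degenerate life tables for closed-form limits
zero_mort_table <- function(max_age = 160) {
  gompertz_life_table(a = 0, b = 0, c = 0, max_age = max_age)
}

const_mort_table <- function(q, max_age = 160) {
  gompertz_life_table(a = 0, b = 0, c = q, max_age = max_age)
}

# the bundled synthetic UK-like reproduction table
fixture_life_table <- function() {
  read_life_table(system.file("extdata", "life_table_synthetic_uk.csv",
                              package = "lvohta", mustWork = TRUE))
}

point_mass <- function(state) {
  p <- rep(0, 7)
  p[state + 1L] <- 1
  mrs_distribution(p)
}

utilities7_for_test <- function(p) c(p$utilities$utility_by_state, 0)

expect_valid_dist <- function(d) {
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(sum(d), 1, tolerance = 1e-12)
}
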