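test_that("transition is the identity without mortality or recurrence", {
  p <- model_params(p_recurrent = 0)
  d <- model_params()$clinical$mrs_iat
  out <- markov_transition(d, 66, p, zero_mort_table())
  expect_equal(as.numeric(out), as.numeric(d))
})

test_that("no improvement: mass from mRS 5 stays in {mRS 5, death} under clamp_max", {
  p <- model_params(p_recurrent = 0.5)
  out <- markov_transition(point_mass(5), 66, p, const_mort_table(0.1))
  expect_equal(sum(out[1:5]), 0)
  expect_valid_dist(out)
})

test_that("two-stage hazard: mortality then recurrence, hand-computed death mass", {
  p <- model_params()  # p_recurrent = 0.0284, mrs_no_iat death share 0.20
  out <- markov_transition(point_mass(0), 66, p, const_mort_table(0.02))
  expect_equal(out[["death"]], 0.02 + 0.98 * 0.0284 * 0.20, tolerance = 1e-12)
})

test_that("truncated-renormalized recurrence also conserves mass and never improves", {
  p <- model_params(recurrence_rule = "truncate_renormalize",
                    p_recurrent = 0.3)
  for (s in 0:5) {
    out <- markov_transition(point_mass(s), 70, p, const_mort_table(0.05))
    expect_valid_dist(out)
    if (s > 0) expect_equal(sum(out[seq_len(s)]), 0)
  }
})

test_that("trajectories conserve probability and death is absorbing", {
  lt <- fixture_life_table()
  for (s in 1:40) {
    p <- random_params(s, 0.3)
    res <- run_markov(mrs_at_90(p, "ai_aided"), p, lt)
    sums <- rowSums(res$trajectory)
    expect_true(all(abs(sums - 1) < 1e-9))
    expect_true(all(diff(res$trajectory[, "death"]) >= -1e-12))
  }
})

test_that("zero-mortality zero-recurrence limits match the closed-form annuities", {
  p <- model_params(p_recurrent = 0)
  res <- run_markov(point_mass(0), p, zero_mort_table())
  qaly_annuity <- 0.95 * (1 - 1.015^-70) / 0.015
  cost_annuity <- 3936 * (1 - 1.04^-70) / 0.04
  expect_equal(res$qaly_pp, qaly_annuity, tolerance = 1e-9)
  expect_equal(res$cost_pp, cost_annuity, tolerance = 1e-9)
})

test_that("absorbed cohorts accrue nothing", {
  p <- model_params()
  res <- run_markov(point_mass(6), p, fixture_life_table())
  expect_equal(res$cost_pp, 0)
  expect_equal(res$qaly_pp, 0)
  expect_equal(unname(res$trajectory[71, "death"]), 1)
})

test_that("stochastic dominance of the seed distribution is preserved in QALYs", {
  p <- model_params()
  lt <- fixture_life_table()
  a <- run_markov(p$clinical$mrs_iat, p, lt)
  b <- run_markov(p$clinical$mrs_no_iat, p, lt)
  expect_gt(a$qaly_pp, b$qaly_pp)
})

test_that("raising the utility discount rate lowers lifetime QALYs", {
  lt <- fixture_life_table()
  q <- vapply(c(0.005, 0.015, 0.05), function(r) {
    p <- model_params(discount_utilities = r)
    run_markov(p$clinical$mrs_iat, p, lt)$qaly_pp
  }, numeric(1))
  expect_true(all(diff(q) < 0))
})

test_that("re-triggered acute costs on recurrence only add cost", {
  lt <- fixture_life_table()
  base <- run_markov(model_params()$clinical$mrs_no_iat, model_params(), lt)
  flag <- model_params(recurrence_acute_costs = TRUE)
  with_flag <- run_markov(flag$clinical$mrs_no_iat, flag, lt)
  expect_gt(with_flag$cost_pp, base$cost_pp)
  expect_equal(with_flag$qaly_pp, base$qaly_pp)
})

test_that("microsimulation oracle is seeded and degenerate cases are exact", {
  p <- model_params()
  lt <- fixture_life_table()
  dead <- microsim_oracle(point_mass(6), p, lt, 500, seed = 3)
  expect_equal(dead$cost_pp, 0)
  expect_equal(dead$qaly_pp, 0)

  a <- microsim_oracle(p$clinical$mrs_iat, p, lt, 2000, seed = 11)
  b <- microsim_oracle(p$clinical$mrs_iat, p, lt, 2000, seed = 11)
  expect_identical(a, b)
  c <- microsim_oracle(p$clinical$mrs_iat, p, lt, 2000, seed = 12)
  expect_false(identical(a$cost_pp, c$cost_pp))
})

test_that("cohort engine agrees with the microsimulation oracle across random draws", {
  lt <- fixture_life_table()
  for (s in c(1, 5, 9, 13, 17)) {
    p <- random_params(s, 0.25)
    dist90 <- mrs_at_90(p, "usual_care")
    cohort <- run_markov(dist90, p, lt)
    ms <- microsim_oracle(dist90, p, lt, 20000, seed = s)
    expect_lt(abs(cohort$cost_pp - ms$cost_pp), 3.5 * ms$se_cost)
    expect_lt(abs(cohort$qaly_pp - ms$qaly_pp), 3.5 * ms$se_qaly)
  }
})

test_that("trajectory CSV export round-trips occupancies at full precision", {
  p <- model_params()
  lt <- fixture_life_table()
  res <- run_markov(p$clinical$mrs_iat, p, lt)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(res, f, p)
  df <- read.csv(f)
  expect_equal(nrow(df), 71)
  expect_equal(as.matrix(df[, 3:9]), unname(res$trajectory),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(sum(df$disc_cost), res$cost_pp, tolerance = 1e-9)
  expect_equal(sum(df$disc_qaly), res$qaly_pp, tolerance = 1e-9)
})
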