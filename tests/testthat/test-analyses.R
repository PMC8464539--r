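test_that("strategies differing only by the fee give ic = fee, ie = 0", {
  lt <- fixture_life_table()
  res <- compare_strategies(model_params(reduction = 0), lt)
  expect_equal(res$ic_pp, 40, tolerance = 1e-9)
  expect_equal(res$ie_pp, 0, tolerance = 1e-12)
  expect_false(res$dominant)
})

test_that("incremental result fields are internally consistent", {
  lt <- fixture_life_table()
  res <- compare_strategies(model_params(), lt)
  # phase additivity, population scaling, NMB arithmetic
  expect_equal(res$acute_ic + res$longterm_ic, res$ic_pp)
  expect_equal(res$acute_ie + res$longterm_ie, res$ie_pp)
  expect_equal(res$ic_pop, res$ic_pp * 71840)
  expect_equal(res$ie_pop, res$ie_pp * 71840)
  expect_equal(res$nmb_pp, 25662 * res$ie_pp - res$ic_pp)
  expect_true(res$dominant)
  expect_true(is.na(res$icer))
  expect_equal(population_scale(res, 1)$ic_pop, res$ic_pp)
  expect_equal(population_scale(res, 71840)$ie_pop, res$ie_pop)
})

test_that("increments depend on miss rate and reduction only through their product", {
  lt <- fixture_life_table()
  g <- scenario_grid(model_params(), lt,
                     missed_values = c(0.03, 0.06, 0.10),
                     reduction_values = c(0.25, 0.50, 1.00), ai_cost = 0)
  # equal products give identical cells (the grid's diagonal symmetry)
  a <- g[g$p_missed == 0.06 & g$reduction == 0.50, ]
  b <- g[g$p_missed == 0.03 & g$reduction == 1.00, ]
  expect_equal(a$ic_pp, b$ic_pp, tolerance = 1e-9)
  expect_equal(a$ie_pp, b$ie_pp, tolerance = 1e-9)
  # linearity: cells scale with m * r
  ref <- g[g$p_missed == 0.03 & g$reduction == 0.25, ]
  for (i in seq_len(nrow(g))) {
    ratio <- (g$p_missed[i] * g$reduction[i]) / (0.03 * 0.25)
    expect_equal(g$ic_pp[i], ref$ic_pp * ratio, tolerance = 1e-8)
    expect_equal(g$ie_pp[i], ref$ie_pp * ratio, tolerance = 1e-8)
  }
  # nothing to detect -> exactly no increment
  z <- scenario_grid(model_params(), lt, 0, 0.5, 0)
  expect_equal(z$ic_pp, 0, tolerance = 1e-12)
  expect_equal(z$ie_pp, 0, tolerance = 1e-12)
})

test_that("incremental cost is affine in the per-analysis price with slope 1", {
  lt <- fixture_life_table()
  m <- price_performance_grid(model_params(), lt,
                              prices = c(0, 40, 120, 200),
                              reductions = c(0, 0.5, 1))
  for (j in 1:3) {
    expect_equal(m[, j] - m[1, j], c(0, 40, 120, 200), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  # zero reduction: the fee is the whole increment
  expect_equal(m[, 1], c(0, 40, 120, 200), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("threshold price is the zero-fee saving and vanishes without benefit", {
  lt <- fixture_life_table()
  p <- model_params()
  expect_equal(threshold_price(p, lt),
               -(compare_strategies(p, lt)$ic_pp - 40), tolerance = 1e-9)
  expect_equal(threshold_price(model_params(reduction = 0), lt), 0,
               tolerance = 1e-12)
})

test_that("one-way sensitivity: spreads, ordering and error handling", {
  lt <- fixture_life_table()
  p <- model_params()
  # zero-width bounds give zero spread
  tr0 <- one_way_sensitivity(p, lt, bounds = list(
    tx_iat = c(11728, 11728), longterm_costs = c(1, 1)))
  expect_equal(tr0$cost_spread, c(0, 0), tolerance = 1e-9)

  tr <- one_way_sensitivity(p, lt, bounds = list(
    acute_costs = c(0.8, 1.2), longterm_costs = c(0.8, 1.2)))
  expect_true(all(diff(tr$cost_spread) <= 0))  # sorted descending
  expect_gt(tr$cost_spread[tr$parameter == "longterm_costs"],
            tr$cost_spread[tr$parameter == "acute_costs"])

  expect_error(one_way_sensitivity(p, lt, bounds = list(bogus = c(0, 1))),
               "unknown sensitivity parameter")
})

test_that("incremental results are invariant to the non-LVO outcome profile", {
  lt <- fixture_life_table()
  r_h <- compare_strategies(model_params(non_lvo_profile = "healthy"), lt)
  r_n <- compare_strategies(model_params(non_lvo_profile = "non_iat"), lt)
  r_c <- compare_strategies(
    model_params(non_lvo_profile = "custom",
                 non_lvo_custom = c(0.3, 0.3, 0.2, 0.1, 0.05, 0.03, 0.02)),
    lt)
  expect_equal(r_h$ic_pp, r_n$ic_pp, tolerance = 1e-8)
  expect_equal(r_h$ie_pp, r_n$ie_pp, tolerance = 1e-10)
  expect_equal(r_h$ic_pp, r_c$ic_pp, tolerance = 1e-8)
  expect_equal(r_h$ie_pp, r_c$ie_pp, tolerance = 1e-10)
  # only the percent-of-usual-care denominators change
  expect_false(isTRUE(all.equal(r_h$pct_cost, r_n$pct_cost)))
})

test_that("QALY gains are non-negative under stochastic dominance of IAT outcomes", {
  lt <- fixture_life_table()
  for (s in 1:10) {
    p <- random_params(s, 0.2)
    cum_iat <- cumsum(as.numeric(p$clinical$mrs_iat))
    cum_no <- cumsum(as.numeric(p$clinical$mrs_no_iat))
    if (all(cum_iat >= cum_no)) {
      expect_gte(compare_strategies(p, lt)$ie_pp, -1e-12)
    }
  }
})
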