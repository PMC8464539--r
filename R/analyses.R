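#' Lifetime (post-90-day) outcomes of one strategy
#'
#' Runs the Markov cohort model separately for the LVO sub-cohort (full
#' recurrence dynamics and long-term stroke costs) and the non-LVO
#' sub-cohort, whose dynamics depend on the configured profile: "healthy"
#' patients face background mortality only and accrue mRS 0 utility at zero
#' long-term cost; "non_iat" and "custom" profiles are modelled as stroke
#' survivors with full dynamics and costs.
#'
#' @inheritParams iat_fraction
#' @param mortality A [life_table].
#' @return List with per-cohort-patient discounted `cost_pp` and `qaly_pp`
#'   and the LVO sub-cohort `lifetime_result`.
#' @export
lifetime_outcomes <- function(params, strategy = c("usual_care", "ai_aided"),
                              mortality) {
  strategy <- match.arg(strategy)
  cl <- params$clinical
  p_lvo <- cl$p_lvo

  lvo <- if (p_lvo > 0) {
    run_markov(lvo_mrs_at_90(params, strategy), params, mortality)
  } else list(cost_pp = 0, qaly_pp = 0, trajectory = NULL)

  non_lvo <- if (p_lvo < 1) {
    if (params$settings$non_lvo_profile == "healthy") {
      run_markov(mrs_distribution(c(1, 0, 0, 0, 0, 0, 0)), params, mortality,
                 longterm_costs = rep(0, 6), p_recurrent = 0)
    } else {
      run_markov(non_lvo_dist(params), params, mortality)
    }
  } else list(cost_pp = 0, qaly_pp = 0)

  list(
    cost_pp = p_lvo * lvo$cost_pp + (1 - p_lvo) * non_lvo$cost_pp,
    qaly_pp = p_lvo * lvo$qaly_pp + (1 - p_lvo) * non_lvo$qaly_pp,
    lvo = lvo
  )
}

#' Compare the AI-aided strategy against usual care
#'
#' Runs the acute-phase decision tree and the lifetime Markov model for both
#' strategies and reports the full incremental result: per-patient and
#' population incremental costs and QALYs (AI minus usual care), phase
#' decomposition, percent of usual-care absolute totals, net monetary
#' benefit at the configured willingness-to-pay, dominance, and the ICER
#' when the AI strategy is not dominant.
#'
#' @param params `lvo_model_params`.
#' @param mortality A [life_table].
#' @return An object of class `incremental_result`.
#' @export
compare_strategies <- function(params, mortality) {
  acute_uc <- acute_outcomes(params, "usual_care")
  acute_ai <- acute_outcomes(params, "ai_aided")
  life_uc <- lifetime_outcomes(params, "usual_care", mortality)
  life_ai <- lifetime_outcomes(params, "ai_aided", mortality)

  acute_ic <- acute_ai$cost_pp - acute_uc$cost_pp
  acute_ie <- acute_ai$qaly_pp - acute_uc$qaly_pp
  life_ic <- life_ai$cost_pp - life_uc$cost_pp
  life_ie <- life_ai$qaly_pp - life_uc$qaly_pp
  ic_pp <- acute_ic + life_ic
  ie_pp <- acute_ie + life_ie

  uc_cost <- acute_uc$cost_pp + life_uc$cost_pp
  uc_qaly <- acute_uc$qaly_pp + life_uc$qaly_pp
  n <- params$clinical$cohort_n
  wtp <- params$settings$wtp_per_qaly
  dominant <- ic_pp <= 0 && ie_pp >= 0

  structure(list(
    ic_pp = ic_pp, ie_pp = ie_pp,
    ic_pop = ic_pp * n, ie_pop = ie_pp * n,
    pct_cost = if (uc_cost > 0) 100 * ic_pp / uc_cost else NA_real_,
    pct_qaly = if (uc_qaly > 0) 100 * ie_pp / uc_qaly else NA_real_,
    nmb_pp = wtp * ie_pp - ic_pp,
    dominant = dominant,
    icer = if (!dominant && ie_pp != 0) ic_pp / ie_pp else NA_real_,
    acute_ic = acute_ic, acute_ie = acute_ie,
    longterm_ic = life_ic, longterm_ie = life_ie,
    usual_cost_pp = uc_cost, usual_qaly_pp = uc_qaly,
    cohort_n = n, wtp_per_qaly = wtp
  ), class = "incremental_result")
}

#' @export
print.incremental_result <- function(x, ...) {
  cat("AI-aided vs usual care, per suspected-stroke patient:\n")
  cat(sprintf("  incremental cost  $%.0f  (acute $%.0f, rest of life $%.0f)\n",
              x$ic_pp, x$acute_ic, x$longterm_ic))
  cat(sprintf("  incremental QALYs %+.4f (acute %+.4f, rest of life %+.4f)\n",
              x$ie_pp, x$acute_ie, x$longterm_ie))
  cat(sprintf("  population (n = %d): cost $%.0f, QALYs %.1f\n",
              x$cohort_n, x$ic_pop, x$ie_pop))
  cat(sprintf("  NMB $%.0f/patient at $%s/QALY; %s\n", x$nmb_pp,
              format(x$wtp_per_qaly, big.mark = ","),
              if (x$dominant) "AI strategy dominant"
              else sprintf("ICER $%.0f/QALY", x$icer)))
  invisible(x)
}

#' Scenario grid over miss rate and AI performance
#'
#' Evaluates the full model once per combination of the standard-care miss
#' rate and the AI reduction of missed LVOs, with the per-analysis AI fee
#' overridden (default $0, so each cell's cost saving is the headroom price
#' at which the tool is dominant).
#'
#' @param params `lvo_model_params`.
#' @param mortality A [life_table].
#' @param missed_values Miss-rate fractions in `[0, 1]`.
#' @param reduction_values Reduction fractions in `[0, 1]`.
#' @param ai_cost Per-analysis fee applied in every cell.
#' @return Data frame (row-major in `p_missed` then `reduction`) with
#'   columns `p_missed`, `reduction`, `ai_cost`, `ic_pp`, `ie_pp`.
#' @export
scenario_grid <- function(params, mortality,
                          missed_values = c(0.01, 0.03, 0.06, 0.10, 0.20),
                          reduction_values = c(0.01, 0.25, 0.50, 0.75, 1.00),
                          ai_cost = 0) {
  stopifnot(all(missed_values >= 0 & missed_values <= 1),
            all(reduction_values >= 0 & reduction_values <= 1),
            ai_cost >= 0)
  cells <- expand.grid(reduction = reduction_values, p_missed = missed_values,
                       KEEP.OUT.ATTRS = FALSE)[, c("p_missed", "reduction")]
  res <- lapply(seq_len(nrow(cells)), function(i) {
    p <- params
    p$clinical$p_missed <- cells$p_missed[i]
    p$clinical$reduction <- cells$reduction[i]
    p$costs$ai_per_analysis <- ai_cost
    r <- compare_strategies(p, mortality)
    c(ic_pp = r$ic_pp, ie_pp = r$ie_pp)
  })
  cbind(cells, ai_cost = ai_cost, do.call(rbind, res))
}

#' Incremental cost over a price-performance grid
#'
#' Incremental per-patient cost of the AI strategy at each combination of
#' per-analysis price and reduction of missed LVOs (miss rate and all other
#' parameters at their configured values). By construction the fee applies
#' to every analyzed patient, so each column satisfies
#' `ic_pp(price) = ic_pp(0) + price` exactly.
#'
#' @param params `lvo_model_params`.
#' @param mortality A [life_table].
#' @param prices Per-analysis prices (>= 0).
#' @param reductions Reduction fractions in `[0, 1]`.
#' @return Numeric matrix of `ic_pp`, rows indexed by price, columns by
#'   reduction.
#' @export
price_performance_grid <- function(params, mortality,
                                   prices = seq(0, 200, by = 20),
                                   reductions = seq(0, 1, by = 0.1)) {
  stopifnot(all(prices >= 0), all(reductions >= 0 & reductions <= 1))
  out <- matrix(NA_real_, length(prices), length(reductions),
                dimnames = list(price = prices, reduction = reductions))
  for (j in seq_along(reductions)) {
    for (i in seq_along(prices)) {
      p <- params
      p$clinical$reduction <- reductions[j]
      p$costs$ai_per_analysis <- prices[i]
      out[i, j] <- compare_strategies(p, mortality)$ic_pp
    }
  }
  out
}

#' Threshold (headroom) price per AI analysis
#'
#' The maximum per-analysis price at which the AI strategy remains dominant:
#' the price `p*` solving `ic_pp(p*) = 0`. Since the fee enters the
#' incremental cost with slope exactly 1, `p*` equals the cost saving at a
#' zero fee.
#'
#' @param params `lvo_model_params`.
#' @param mortality A [life_table].
#' @return Threshold price in USD (unrounded; reports round to the dollar).
#' @export
threshold_price <- function(params, mortality) {
  p <- params
  p$costs$ai_per_analysis <- 0
  -compare_strategies(p, mortality)$ic_pp
}

default_tornado_bounds <- function(params) {
  cl <- params$clinical; co <- params$costs; ut <- params$utilities
  list(
    p_lvo              = c(0.8 * cl$p_lvo, min(1, 1.2 * cl$p_lvo)),
    p_eligible         = c(0.8, 1.2) * cl$p_eligible,
    p_recurrent        = c(0.8, 1.2) * cl$p_recurrent,
    tx_iat             = c(0.8, 1.2) * co$tx_iat,
    tx_no_iat          = c(0.8, 1.2) * co$tx_no_iat,
    acute_costs        = c(0.8, 1.2),
    longterm_costs     = c(0.8, 1.2),
    utilities          = c(0.8, 1.2),
    age0               = c(cl$age0 - 10L, cl$age0 + 10L),
    discount_costs     = c(0.8, 1.2) * co$discount_costs,
    discount_utilities = c(0.8, 1.2) * ut$discount_utilities
  )
}

set_tornado_param <- function(params, name, value) {
  p <- params
  switch(name,
    p_lvo              = { p$clinical$p_lvo <- min(1, value) },
    p_eligible         = { p$clinical$p_eligible <- min(1, value) },
    p_recurrent        = { p$clinical$p_recurrent <- min(1, value) },
    tx_iat             = { p$costs$tx_iat <- value },
    tx_no_iat          = { p$costs$tx_no_iat <- value },
    acute_costs        = { p$costs$acute_by_state <-
                             p$costs$acute_by_state * value },
    longterm_costs     = { p$costs$longterm_by_state <-
                             p$costs$longterm_by_state * value },
    utilities          = { p$utilities$utility_by_state <-
                             pmin(1, p$utilities$utility_by_state * value) },
    age0               = { p$clinical$age0 <- as.integer(max(18, value)) },
    discount_costs     = { p$costs$discount_costs <- min(0.2, value) },
    discount_utilities = { p$utilities$discount_utilities <-
                             min(0.2, value) },
    stop("unknown sensitivity parameter: ", name, call. = FALSE)
  )
  p
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the strategy comparison with each named parameter set to its low
#' and high bound, all else held at the base case, and returns rows sorted
#' by the induced incremental-cost spread (tornado order). Vector-valued
#' parameters (`acute_costs`, `longterm_costs`, `utilities`) take
#' multiplicative bounds; scalars take absolute bounds. Defaults are +/-20\%
#' around the base case and +/-10 years on the starting age.
#'
#' @param params `lvo_model_params`.
#' @param mortality A [life_table].
#' @param bounds Named list of `c(low, high)` pairs; names from
#'   `p_lvo, p_eligible, p_recurrent, tx_iat, tx_no_iat, acute_costs,
#'   longterm_costs, utilities, age0, discount_costs, discount_utilities`.
#' @return Data frame with columns `parameter`, `low`, `high`, `ic_low`,
#'   `ic_high`, `ie_low`, `ie_high`, `cost_spread`, sorted by `cost_spread`
#'   descending.
#' @export
one_way_sensitivity <- function(params, mortality,
                                bounds = default_tornado_bounds(params)) {
  if (is.null(names(bounds)) || any(names(bounds) == ""))
    stop("bounds must be a named list of c(low, high) pairs", call. = FALSE)
  rows <- lapply(names(bounds), function(nm) {
    b <- bounds[[nm]]
    if (length(b) != 2L || b[1] > b[2])
      stop("bounds for ", nm, " must be an ordered pair c(low, high)",
           call. = FALSE)
    lo <- compare_strategies(set_tornado_param(params, nm, b[1]), mortality)
    hi <- compare_strategies(set_tornado_param(params, nm, b[2]), mortality)
    data.frame(parameter = nm, low = b[1], high = b[2],
               ic_low = lo$ic_pp, ic_high = hi$ic_pp,
               ie_low = lo$ie_pp, ie_high = hi$ie_pp,
               cost_spread = abs(hi$ic_pp - lo$ic_pp))
  })
  out <- do.call(rbind, rows)
  out[order(-out$cost_spread), , drop = FALSE]
}

#' Scale per-patient increments to a yearly cohort
#'
#' @param result An `incremental_result` from [compare_strategies()].
#' @param cohort_n Yearly cohort size (> 0).
#' @return List with `ic_pop` and `ie_pop`.
#' @export
population_scale <- function(result, cohort_n) {
  stopifnot(inherits(result, "incremental_result"), cohort_n > 0)
  list(ic_pop = result$ic_pp * cohort_n, ie_pop = result$ie_pp * cohort_n)
}
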