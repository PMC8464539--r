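#' Probability that an LVO is detected
#'
#' Under usual care a fraction `p_missed` of large vessel occlusions is
#' missed on CTA; the AI-aided strategy recovers a fraction `reduction` of
#' those misses without changing specificity.
#'
#' @param strategy `"usual_care"` or `"ai_aided"`.
#' @param p_missed Miss rate of LVOs in standard care, in `[0, 1]`.
#' @param reduction Fraction of missed LVOs recovered by the AI aid.
#' @return Detection probability: `1 - p_missed` for usual care,
#'   `1 - p_missed * (1 - reduction)` for the AI strategy.
#' @examples
#' detection_rate("usual_care", 0.06)        # 0.94
#' detection_rate("ai_aided", 0.06, 0.5)     # 0.97
#' @export
detection_rate <- function(strategy = c("usual_care", "ai_aided"),
                           p_missed, reduction = 0) {
  strategy <- match.arg(strategy)
  if (any(p_missed < 0 | p_missed > 1) || any(reduction < 0 | reduction > 1))
    stop("p_missed and reduction must lie in [0, 1]", call. = FALSE)
  if (strategy == "usual_care") 1 - p_missed
  else 1 - p_missed * (1 - reduction)
}

#' Fraction of the cohort treated with thrombectomy
#'
#' Only detected, IAT-eligible LVO patients receive intra-arterial
#' thrombectomy: the product of LVO prevalence, eligibility and the
#' strategy's detection rate. Eligibility is treated as independent of
#' detection.
#'
#' @param params `lvo_model_params`.
#' @param strategy `"usual_care"` or `"ai_aided"`.
#' @return Fraction in `[0, p_lvo * p_eligible]`.
#' @export
iat_fraction <- function(params, strategy = c("usual_care", "ai_aided")) {
  strategy <- match.arg(strategy)
  cl <- params$clinical
  cl$p_lvo * cl$p_eligible *
    detection_rate(strategy, cl$p_missed, cl$reduction)
}

#' Expectation of a per-state value under an mRS distribution
#'
#' The probability-weighted sum used throughout for expected costs and
#' utilities. The value vector must cover every state the distribution
#' weights (length 7, mRS 0-5 and death).
#'
#' @param dist An [mrs_distribution()].
#' @param values Numeric vector of length 7 (per-state values, death last).
#' @return Scalar expectation.
#' @export
expected_over_states <- function(dist, values) {
  if (!is_mrs_distribution(dist))
    stop("dist must be a valid mrs_distribution", call. = FALSE)
  if (length(values) != length(dist))
    stop("values must supply one entry per state (length 7)", call. = FALSE)
  sum(as.numeric(dist) * as.numeric(values))
}

# utilities padded with death = 0, for use with 7-state distributions
utilities7 <- function(params) c(params$utilities$utility_by_state, 0)

# 90-day mRS distribution of the non-LVO branch, per configured profile
non_lvo_dist <- function(params) {
  se <- params$settings
  switch(se$non_lvo_profile,
    healthy = mrs_distribution(c(1, 0, 0, 0, 0, 0, 0)),
    non_iat = params$clinical$mrs_no_iat,
    custom  = {
      if (!is_mrs_distribution(se$non_lvo_custom))
        stop("non_lvo_profile 'custom' requires a non_lvo_custom distribution",
             call. = FALSE)
      se$non_lvo_custom
    }
  )
}

# 90-day distribution of LVO patients only (IAT-treated vs not)
lvo_mrs_at_90 <- function(params, strategy) {
  cl <- params$clinical
  f <- iat_fraction(params, strategy)
  w <- if (cl$p_lvo > 0) f / cl$p_lvo else 0
  mrs_distribution(w * as.numeric(cl$mrs_iat) +
                   (1 - w) * as.numeric(cl$mrs_no_iat))
}

#' Cohort mRS distribution at 90 days
#'
#' Evaluates the acute-phase decision tree: detected eligible LVO patients
#' follow the with-IAT outcome distribution, remaining LVO patients the
#' without-IAT distribution, and non-LVO patients the configured profile
#' (default "healthy": a point mass at mRS 0). This distribution seeds the
#' lifetime Markov model.
#'
#' @inheritParams iat_fraction
#' @return An [mrs_distribution()] over the whole cohort.
#' @export
mrs_at_90 <- function(params, strategy = c("usual_care", "ai_aided")) {
  strategy <- match.arg(strategy)
  cl <- params$clinical
  f <- iat_fraction(params, strategy)
  mrs_distribution(
    f * as.numeric(cl$mrs_iat) +
    (cl$p_lvo - f) * as.numeric(cl$mrs_no_iat) +
    (1 - cl$p_lvo) * as.numeric(non_lvo_dist(params))
  )
}

#' Acute-phase (first 90 days) outcomes of one strategy
#'
#' Expected per-patient cost and QALYs over the first 90 days, plus the
#' 90-day cohort mRS distribution. Costs comprise treatment (IAT-eligible
#' average vs non-eligible average for LVO patients), per-state acute stroke
#' costs, the per-analysis AI fee in the AI arm (every CTA patient is
#' screened), and an optional linear false-positive reading-time cost hook.
#' Acute utility accrues over `acute_year_fraction` of a year (default
#' 90/365.25) at the 90-day state's utility; the acute phase is undiscounted.
#'
#' @inheritParams iat_fraction
#' @return An object of class `acute_result` with fields `cost_pp`,
#'   `qaly_pp`, `dist90`, `f_iat`.
#' @export
acute_outcomes <- function(params, strategy = c("usual_care", "ai_aided")) {
  strategy <- match.arg(strategy)
  cl <- params$clinical; co <- params$costs; se <- params$settings
  f <- iat_fraction(params, strategy)
  dist90 <- mrs_at_90(params, strategy)

  tx_cost <- f * co$tx_iat + (cl$p_lvo - f) * co$tx_no_iat
  lvo_state_cost <- if (cl$p_lvo > 0) {
    cl$p_lvo * expected_over_states(lvo_mrs_at_90(params, strategy),
                                    co$acute_by_state)
  } else 0
  non_lvo_state_cost <- if (se$non_lvo_profile == "healthy") 0 else {
    (1 - cl$p_lvo) * expected_over_states(non_lvo_dist(params),
                                          co$acute_by_state)
  }
  ai_cost <- if (strategy == "ai_aided") {
    co$ai_per_analysis + se$fp_rate_points * co$fp_cost_per_point
  } else 0

  cost_pp <- tx_cost + lvo_state_cost + non_lvo_state_cost + ai_cost
  qaly_pp <- se$acute_year_fraction *
    expected_over_states(dist90, utilities7(params))

  structure(list(cost_pp = cost_pp, qaly_pp = qaly_pp,
                 dist90 = dist90, f_iat = f, strategy = strategy),
            class = "acute_result")
}

#' @export
print.acute_result <- function(x, ...) {
  cat(sprintf("acute phase (%s): cost $%.2f, QALYs %.5f, IAT fraction %.4f\n",
              x$strategy, x$cost_pp, x$qaly_pp, x$f_iat))
  invisible(x)
}

#' Acute-phase increment of the AI strategy over usual care
#'
#' @param params `lvo_model_params`.
#' @return Named numeric vector `c(cost = ..., qaly = ...)`: AI-aided minus
#'   usual-care per-patient acute cost and QALYs.
#' @export
incremental_acute <- function(params) {
  ai <- acute_outcomes(params, "ai_aided")
  uc <- acute_outcomes(params, "usual_care")
  c(cost = ai$cost_pp - uc$cost_pp, qaly = ai$qaly_pp - uc$qaly_pp)
}
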