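# 7x7 within-cycle recurrence redistribution matrix (rows = current state,
# cols = destination). Recurrent stroke outcomes follow the without-IAT mRS
# distribution under a no-improvement constraint: either the draw is clamped
# to max(current, draw) or the distribution is truncated to states >= current
# and renormalized (death included either way).
recurrence_matrix <- function(mrs_no_iat, rule = c("clamp_max",
                                                  "truncate_renormalize")) {
  rule <- match.arg(rule)
  q <- as.numeric(mrs_no_iat)
  R <- matrix(0, 7, 7, dimnames = list(MRS_STATES, MRS_STATES))
  for (s in 1:6) {
    if (rule == "clamp_max") {
      R[s, s] <- sum(q[1:s])
      if (s < 6) R[s, (s + 1):6] <- q[(s + 1):6]
      R[s, 7] <- q[7]
    } else {
      w <- c(rep(0, s - 1), q[s:7])
      tot <- sum(w)
      R[s, ] <- if (tot > 0) w / tot else c(rep(0, 6), 1)
    }
  }
  R[7, 7] <- 1
  R
}

# one yearly cycle: background mortality first, then recurrent stroke among
# survivors. Returns the new distribution and the mass flowing through a
# recurrent stroke into each destination state (for optional acute-cost
# re-triggering).
transition_step <- function(dist, age, params, mortality,
                            R = recurrence_matrix(
                              params$clinical$mrs_no_iat,
                              params$settings$recurrence_rule)) {
  p <- as.numeric(dist)
  qx <- qx_at(mortality, age)
  alive <- p[1:6] * (1 - qx)
  dead <- p[7] + sum(p[1:6]) * qx

  pr <- params$clinical$p_recurrent
  recur_in <- pr * as.numeric(c(alive, 0) %*% R)
  new_alive <- (1 - pr) * alive + recur_in[1:6]
  out <- c(new_alive, dead + recur_in[7])
  list(dist = out, recur_in = recur_in)
}

#' One yearly Markov cycle
#'
#' Applies sequential within-cycle hazards to a cohort distribution: (1)
#' every alive state loses mass to death at the age-specific background
#' probability `qx(age)`; (2) survivors suffer a recurrent stroke with
#' probability `p_recurrent`, redistributing by the configured recurrence
#' rule (no improvement possible); (3) everyone else remains in place.
#'
#' @param dist An [mrs_distribution()].
#' @param age Age in years at the start of the cycle (plateau-extrapolated
#'   beyond the table's end).
#' @param params `lvo_model_params`.
#' @param mortality A [life_table].
#' @return The end-of-cycle [mrs_distribution()].
#' @export
markov_transition <- function(dist, age, params, mortality) {
  if (!is_mrs_distribution(dist))
    stop("dist must be a valid mrs_distribution", call. = FALSE)
  out <- transition_step(dist, age, params, mortality)$dist
  structure(setNames(out, MRS_STATES), class = "mrs_distribution")
}

#' Lifetime Markov cohort model
#'
#' Propagates a 90-day mRS distribution through yearly cycles (default 70)
#' with background mortality and recurrent-stroke worsening, accruing
#' end-of-cycle discounted costs and QALYs. Cycle `t` uses mortality at age
#' `age0 + t - 1`, cost discount factor `(1 + discount_costs)^-t` and
#' utility discount factor `(1 + discount_utilities)^-t`; there is no
#' half-cycle correction. Death accrues nothing.
#'
#' @param dist90 Starting [mrs_distribution()] (the cohort at day 90).
#' @param params `lvo_model_params`.
#' @param mortality A [life_table].
#' @param longterm_costs Annual per-state costs for mRS 0-5; defaults to the
#'   parameterized long-term stroke costs. Supply zeros for a never-stroke
#'   sub-cohort.
#' @param p_recurrent Annual recurrent-stroke probability; defaults to the
#'   parameterized value. Supply 0 for a never-stroke sub-cohort.
#' @return An object of class `lifetime_result` with `cost_pp`, `qaly_pp`
#'   (per-patient discounted totals over the horizon) and `trajectory`, a
#'   `(cycles + 1) x 7` occupancy matrix whose first row is `dist90`.
#' @export
run_markov <- function(dist90, params, mortality,
                       longterm_costs = params$costs$longterm_by_state,
                       p_recurrent = params$clinical$p_recurrent) {
  if (!is_mrs_distribution(dist90))
    stop("dist90 must be a valid mrs_distribution", call. = FALSE)
  if (length(longterm_costs) != 6L || any(longterm_costs < 0))
    stop("longterm_costs must be 6 non-negative annual costs", call. = FALSE)
  params$clinical$p_recurrent <- p_recurrent

  se <- params$settings; co <- params$costs; ut <- params$utilities
  n_cycles <- se$cycles
  age0 <- params$clinical$age0
  u <- ut$utility_by_state

  occupancy <- matrix(NA_real_, n_cycles + 1L, 7L,
                      dimnames = list(cycle = 0:n_cycles, state = MRS_STATES))
  occupancy[1L, ] <- as.numeric(dist90)
  cost <- 0; qaly <- 0
  cur <- as.numeric(dist90)
  R <- recurrence_matrix(params$clinical$mrs_no_iat, se$recurrence_rule)
  for (t in seq_len(n_cycles)) {
    step <- transition_step(cur, age0 + t - 1L, params, mortality, R)
    cur <- step$dist
    occupancy[t + 1L, ] <- cur
    dc <- (1 + co$discount_costs)^(-t)
    du <- (1 + ut$discount_utilities)^(-t)
    cycle_cost <- sum(cur[1:6] * longterm_costs)
    if (se$recurrence_acute_costs)
      cycle_cost <- cycle_cost + sum(step$recur_in * co$acute_by_state)
    cost <- cost + dc * cycle_cost
    qaly <- qaly + du * sum(cur[1:6] * u)
  }
  structure(list(cost_pp = cost, qaly_pp = qaly, trajectory = occupancy),
            class = "lifetime_result")
}

#' @export
print.lifetime_result <- function(x, ...) {
  n <- nrow(x$trajectory) - 1L
  cat(sprintf(
    "lifetime Markov result (%d cycles): cost $%.2f, QALYs %.4f, final death occupancy %.4f\n",
    n, x$cost_pp, x$qaly_pp, x$trajectory[n + 1L, 7L]))
  invisible(x)
}

#' Export a Markov trajectory as CSV
#'
#' Writes one row per cycle: cycle index, age, the seven state occupancies,
#' and the discounted cost and QALYs accrued in that cycle.
#'
#' @param result A `lifetime_result` from [run_markov()].
#' @param path Output file path.
#' @param params The `lvo_model_params` used for the run (for age, discount
#'   rates and cost vectors).
#' @param longterm_costs Annual per-state costs used in the run.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(result, path, params,
                                 longterm_costs = params$costs$longterm_by_state) {
  occ <- result$trajectory
  n <- nrow(occ) - 1L
  t <- 0:n
  dc <- ifelse(t == 0, 0, (1 + params$costs$discount_costs)^(-t))
  du <- ifelse(t == 0, 0, (1 + params$utilities$discount_utilities)^(-t))
  df <- data.frame(
    cycle = t,
    age = params$clinical$age0 + t - 1L,
    occ,
    disc_cost = dc * as.numeric(occ[, 1:6] %*% longterm_costs),
    disc_qaly = du * as.numeric(occ[, 1:6] %*%
                                  params$utilities$utility_by_state)
  )
  df$age[1] <- params$clinical$age0
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Microsimulation oracle for the cohort Markov engine
#'
#' Simulates individual patients under exactly the cohort model's rules —
#' initial state drawn from `dist90`, then per cycle a background-mortality
#' Bernoulli draw followed by a recurrence draw redistributing by the
#' configured rule — and reports mean discounted cost and QALYs with
#' Monte-Carlo standard errors. Used as an independent cross-check of
#' [run_markov()]; identical seeds give identical output.
#'
#' @inheritParams run_markov
#' @param n_patients Number of simulated patients (>= 1).
#' @param seed Integer seed.
#' @return List with `cost_pp`, `qaly_pp`, `se_cost`, `se_qaly`,
#'   `n_patients`.
#' @export
microsim_oracle <- function(dist90, params, mortality, n_patients,
                            seed = params$settings$seed,
                            longterm_costs = params$costs$longterm_by_state,
                            p_recurrent = params$clinical$p_recurrent) {
  if (!is_mrs_distribution(dist90))
    stop("dist90 must be a valid mrs_distribution", call. = FALSE)
  stopifnot(n_patients >= 1)
  n <- as.integer(n_patients)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  se <- params$settings; co <- params$costs; ut <- params$utilities
  n_cycles <- se$cycles
  age0 <- params$clinical$age0
  u <- ut$utility_by_state
  rule <- se$recurrence_rule
  q_no_iat <- as.numeric(params$clinical$mrs_no_iat)

  # states coded 1..7 (mrs0..mrs5, death = 7)
  state <- sample.int(7L, n, replace = TRUE, prob = as.numeric(dist90))
  cost <- numeric(n); qaly <- numeric(n)
  for (t in seq_len(n_cycles)) {
    alive <- state != 7L
    if (!any(alive)) break
    idx <- which(alive)
    qx <- qx_at(mortality, age0 + t - 1L)
    dies <- runif(length(idx)) < qx
    state[idx[dies]] <- 7L
    surv <- idx[!dies]
    if (length(surv) && p_recurrent > 0) {
      rec <- surv[runif(length(surv)) < p_recurrent]
      if (length(rec)) {
        if (rule == "clamp_max") {
          draw <- sample.int(7L, length(rec), replace = TRUE, prob = q_no_iat)
          state[rec] <- pmax(state[rec], draw)
        } else {
          for (i in seq_along(rec)) {
            s <- state[rec[i]]
            w <- c(rep(0, s - 1L), q_no_iat[s:7])
            state[rec[i]] <- sample.int(7L, 1L, prob = w)
          }
        }
      }
    } else rec <- integer(0)
    alive <- state != 7L
    dc <- (1 + co$discount_costs)^(-t)
    du <- (1 + ut$discount_utilities)^(-t)
    if (se$recurrence_acute_costs && length(rec))
      cost[rec] <- cost[rec] + dc * co$acute_by_state[state[rec]]
    cost[alive] <- cost[alive] + dc * longterm_costs[state[alive]]
    qaly[alive] <- qaly[alive] + du * u[state[alive]]
  }
  list(cost_pp = mean(cost), qaly_pp = mean(qaly),
       se_cost = stats::sd(cost) / sqrt(n),
       se_qaly = stats::sd(qaly) / sqrt(n),
       n_patients = n)
}
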