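#' @importFrom stats runif setNames
#' @importFrom utils modifyList read.csv write.csv
NULL

MRS_STATES <- c("mrs0", "mrs1", "mrs2", "mrs3", "mrs4", "mrs5", "death")

#' Probability distribution over modified Rankin Scale states
#'
#' Constructs the model's health-state currency: a probability vector over
#' mRS 0-5 plus death (mRS 6). Inputs whose sum deviates from 1 by at most
#' 0.5\% (as printed rounded percentages do) are renormalized to sum exactly
#' to 1; larger deviations are rejected.
#'
#' @param p Numeric vector of length 7: probabilities for mRS 0, 1, 2, 3, 4,
#'   5 and death, in that order. Percentages on the 0-100 scale are not
#'   accepted; divide by 100 first.
#' @return A named numeric vector of class `mrs_distribution` summing to 1.
#' @examples
#' mrs_distribution(c(0.11, 0.18, 0.20, 0.17, 0.16, 0.04, 0.14))
#' @export
mrs_distribution <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 7L) {
    stop("mrs_distribution needs 7 entries (mRS 0-5 and death), got ",
         length(p), call. = FALSE)
  }
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("mrs_distribution entries must lie in [0, 1]", call. = FALSE)
  }
  s <- sum(p)
  if (abs(s - 1) > 0.005) {
    stop(sprintf(
      "mrs_distribution entries sum to %.6f; must be within 0.5%% of 1", s),
      call. = FALSE)
  }
  structure(setNames(p / s, MRS_STATES), class = "mrs_distribution")
}

#' @export
print.mrs_distribution <- function(x, ...) {
  cat("mRS distribution (mRS 0-5, death):\n")
  print(round(unclass(x), 4))
  invisible(x)
}

is_mrs_distribution <- function(x) {
  inherits(x, "mrs_distribution") && length(x) == 7L &&
    all(x >= 0) && all(x <= 1) && abs(sum(x) - 1) <= 1e-9
}

# ---- defaults: the published base-case parameterization -------------------

default_clinical <- function() {
  list(
    p_lvo       = 0.306,
    p_eligible  = 0.438,
    p_missed    = 0.06,
    reduction   = 0.50,
    p_recurrent = 0.0284,
    age0        = 66L,
    cohort_n    = 71840L,
    mrs_iat     = mrs_distribution(c(0.11, 0.18, 0.20, 0.17, 0.16, 0.04, 0.14)),
    mrs_no_iat  = mrs_distribution(c(0.05, 0.08, 0.11, 0.17, 0.27, 0.12, 0.20))
  )
}

default_costs <- function() {
  list(
    acute_by_state    = c(4350, 5117, 5885, 22695, 30704, 36468, 4603),
    longterm_by_state = c(3936, 4631, 5325, 18944, 25631, 41621),
    tx_iat            = 11728,
    tx_no_iat         = 1004,
    ai_per_analysis   = 40,
    discount_costs    = 0.04,
    fp_cost_per_point = 0
  )
}

default_utilities <- function() {
  list(
    utility_by_state   = c(0.95, 0.93, 0.83, 0.62, 0.42, 0.11),
    discount_utilities = 0.015
  )
}

default_settings <- function() {
  list(
    cycles                 = 70L,
    wtp_per_qaly           = 25662,
    acute_year_fraction    = 90 / 365.25,
    non_lvo_profile        = "healthy",
    non_lvo_custom         = NULL,
    recurrence_rule        = "clamp_max",
    recurrence_acute_costs = FALSE,
    fp_rate_points         = 0,
    seed                   = 1L
  )
}

#' Full model parameterization
#'
#' Assembles the complete parameter set of the cost-effectiveness model:
#' clinical probabilities and 90-day mRS outcome distributions, per-state
#' costs, state utilities, and analysis settings. Called with no arguments it
#' returns the published base case (6\% missed LVOs, 50\% reduction through
#' AI, $40 per analysis, UK cohort of 71,840 starting at age 66).
#'
#' Any field may be overridden by name; unknown names are an error. The
#' result is validated against all type invariants and construction fails
#' with the aggregated list of violations.
#'
#' @param ... Named overrides of individual fields (flat, e.g. `p_missed =
#'   0.2`, `mrs_iat = c(...)`, `ai_per_analysis = 0`).
#' @return A validated object of class `lvo_model_params` with components
#'   `clinical`, `costs`, `utilities`, `settings`.
#' @examples
#' p <- model_params()                 # base case
#' p2 <- model_params(p_missed = 0.2)  # single-field override
#' @export
model_params <- function(...) {
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1]]) &&
      is.null(names(overrides))) {
    overrides <- overrides[[1]]
  }
  build_params(overrides)
}

param_groups <- function() {
  list(
    clinical  = names(default_clinical()),
    costs     = names(default_costs()),
    utilities = names(default_utilities()),
    settings  = names(default_settings())
  )
}

build_params <- function(overrides) {
  groups <- param_groups()
  known <- unlist(groups, use.names = FALSE)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("all parameter overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(overrides), known)
    if (length(unknown)) {
      stop("unknown parameter name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  params <- list(
    clinical  = default_clinical(),
    costs     = default_costs(),
    utilities = default_utilities(),
    settings  = default_settings()
  )
  for (nm in names(overrides)) {
    grp <- names(groups)[vapply(groups, function(g) nm %in% g, logical(1))][1]
    val <- overrides[[nm]]
    if (nm %in% c("mrs_iat", "mrs_no_iat", "non_lvo_custom") && !is.null(val) &&
        !inherits(val, "mrs_distribution")) {
      val <- mrs_distribution(val)
    }
    if (nm %in% c("age0", "cohort_n", "cycles", "seed")) val <- as.integer(val)
    params[[grp]][[nm]] <- val
  }
  class(params) <- "lvo_model_params"
  violations <- validate_params(params)
  if (length(violations)) {
    stop("invalid model parameters:\n  - ",
         paste(violations, collapse = "\n  - "), call. = FALSE)
  }
  params
}

#' Validate a model parameterization
#'
#' Checks every type invariant of the parameter set and reports violations;
#' it never throws. An empty character vector means the parameters are valid.
#'
#' @param params An object as returned by [model_params()] (validated or not).
#' @return Character vector of human-readable violation descriptions, each
#'   naming the offending field; `character(0)` if all invariants hold.
#' @examples
#' validate_params(model_params())  # character(0)
#' @export
validate_params <- function(params) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  cl <- params$clinical; co <- params$costs
  ut <- params$utilities; se <- params$settings

  prob_fields <- c("p_lvo", "p_eligible", "p_missed", "reduction", "p_recurrent")
  for (nm in prob_fields) {
    x <- cl[[nm]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      add(sprintf("%s must be a probability in [0, 1]", nm))
  }
  if (!is.numeric(cl$age0) || cl$age0 != round(cl$age0) || cl$age0 < 18)
    add("age0 must be an integer >= 18")
  if (!is.numeric(cl$cohort_n) || cl$cohort_n != round(cl$cohort_n) ||
      cl$cohort_n <= 0)
    add("cohort_n must be a positive integer")
  for (nm in c("mrs_iat", "mrs_no_iat")) {
    if (!is_mrs_distribution(cl[[nm]]))
      add(sprintf("%s must be a valid mRS distribution summing to 1", nm))
  }

  if (!is.numeric(co$acute_by_state) || length(co$acute_by_state) != 7L ||
      any(co$acute_by_state < 0))
    add("acute_by_state must be 7 non-negative costs (mRS 0-6)")
  if (!is.numeric(co$longterm_by_state) || length(co$longterm_by_state) != 6L ||
      any(co$longterm_by_state < 0))
    add("longterm_by_state must be 6 non-negative annual costs (mRS 0-5)")
  for (nm in c("tx_iat", "tx_no_iat", "ai_per_analysis", "fp_cost_per_point")) {
    x <- co[[nm]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
      add(sprintf("%s must be a non-negative cost", nm))
  }
  if (!is.numeric(co$discount_costs) || co$discount_costs < 0 ||
      co$discount_costs > 0.2)
    add("discount_costs must lie in [0, 0.2]")

  u <- ut$utility_by_state
  if (!is.numeric(u) || length(u) != 6L || any(u < 0) || any(u > 1))
    add("utility_by_state must be 6 utilities in [0, 1] (mRS 0-5)")
  else if (any(diff(u) > 1e-12))
    add("utility_by_state must be non-increasing from mRS 0 to mRS 5")
  if (!is.numeric(ut$discount_utilities) || ut$discount_utilities < 0 ||
      ut$discount_utilities > 0.2)
    add("discount_utilities must lie in [0, 0.2]")

  if (!is.numeric(se$cycles) || se$cycles != round(se$cycles) || se$cycles < 1)
    add("cycles must be an integer >= 1")
  if (!is.numeric(se$wtp_per_qaly) || se$wtp_per_qaly < 0)
    add("wtp_per_qaly must be non-negative")
  if (!is.numeric(se$acute_year_fraction) || se$acute_year_fraction < 0 ||
      se$acute_year_fraction > 1)
    add("acute_year_fraction must lie in [0, 1]")
  if (!se$non_lvo_profile %in% c("healthy", "non_iat", "custom"))
    add("non_lvo_profile must be one of 'healthy', 'non_iat', 'custom'")
  if (identical(se$non_lvo_profile, "custom") &&
      !is_mrs_distribution(se$non_lvo_custom))
    add("non_lvo_profile 'custom' requires non_lvo_custom mRS distribution")
  if (!se$recurrence_rule %in% c("clamp_max", "truncate_renormalize"))
    add("recurrence_rule must be 'clamp_max' or 'truncate_renormalize'")
  if (!is.logical(se$recurrence_acute_costs) ||
      length(se$recurrence_acute_costs) != 1L)
    add("recurrence_acute_costs must be TRUE or FALSE")
  if (!is.numeric(se$fp_rate_points) || se$fp_rate_points < 0)
    add("fp_rate_points must be non-negative")
  v
}

#' @export
print.lvo_model_params <- function(x, ...) {
  cl <- x$clinical
  cat("LVO detection cost-effectiveness model parameters\n")
  cat(sprintf("  cohort: n = %d, starting age %d, %d yearly cycles\n",
              cl$cohort_n, cl$age0, x$settings$cycles))
  cat(sprintf("  LVO prevalence %.1f%%, IAT-eligible %.1f%%, missed %.1f%%, AI reduction %.0f%%\n",
              100 * cl$p_lvo, 100 * cl$p_eligible, 100 * cl$p_missed,
              100 * cl$reduction))
  cat(sprintf("  AI fee $%s per analysis; discounting: costs %.1f%%, utilities %.1f%%\n",
              format(x$costs$ai_per_analysis), 100 * x$costs$discount_costs,
              100 * x$utilities$discount_utilities))
  invisible(x)
}

# ---- configuration files ---------------------------------------------------

flatten_params <- function(params) {
  out <- c(params$clinical, params$costs, params$utilities, params$settings)
  out$mrs_iat <- as.numeric(out$mrs_iat)
  out$mrs_no_iat <- as.numeric(out$mrs_no_iat)
  if (!is.null(out$non_lvo_custom))
    out$non_lvo_custom <- as.numeric(out$non_lvo_custom)
  out[!vapply(out, is.null, logical(1))]
}

#' Load model parameters from a configuration file
#'
#' Reads a flat YAML (or JSON; YAML is a superset) configuration keyed by the
#' parameter field names and returns a fully validated parameter set. Omitted
#' fields take the published base-case defaults; unknown keys are an error so
#' typos in parameter names cannot pass silently.
#'
#' @param path Path to a UTF-8 YAML/JSON file. An empty file yields the full
#'   default parameterization.
#' @return A validated `lvo_model_params` object.
#' @seealso [save_config()] for the inverse; a documented example ships as
#'   `system.file("extdata/config/base_case.yaml", package = "lvohta")`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop("config parse failure in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) {
    stop("config file '", path, "' must contain a mapping of parameter names",
         call. = FALSE)
  }
  build_params(cfg)
}

#' Serialize model parameters to a configuration file
#'
#' Writes the flat YAML representation read back by [load_config()]; the
#' round trip reproduces the parameter set field for field.
#'
#' @param params A `lvo_model_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(params, path) {
  stopifnot(inherits(params, "lvo_model_params"))
  yaml::write_yaml(flatten_params(params), path, precision = 15L)
  invisible(path)
}

#' Convert pounds sterling to US dollars
#'
#' Utility for willingness-to-pay derivation: multiplies a GBP amount by an
#' exchange rate (default the 2019 average rate of 1.283 USD per GBP used to
#' express all model costs in dollars).
#'
#' @param amount_gbp Non-negative amount in GBP.
#' @param rate Positive exchange rate in USD per GBP.
#' @return The amount in USD.
#' @examples
#' convert_currency(20000)  # the 20,000 GBP/QALY reference value in USD
#' @export
convert_currency <- function(amount_gbp, rate = 1.283) {
  if (any(amount_gbp < 0)) stop("amount_gbp must be non-negative", call. = FALSE)
  if (any(rate <= 0)) stop("rate must be positive", call. = FALSE)
  amount_gbp * rate
}
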