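#' Life tables: age-specific annual death probabilities
#'
#' A `life_table` is a data frame with integer column `age` (contiguous,
#' ascending) and numeric column `qx`, the annual probability of dying within
#' the year at that age. It drives background mortality in the Markov model.
#' Lookups beyond the last tabulated age return the final `qx` (plateau
#' extrapolation), so a cohort can always be run past the table's end.
#'
#' @name life_table
NULL

new_life_table <- function(ages, qx) {
  ages <- as.integer(ages)
  qx <- as.numeric(qx)
  if (length(ages) != length(qx) || length(ages) < 1L)
    stop("life table needs matching, non-empty age and qx columns",
         call. = FALSE)
  if (anyNA(ages) || anyNA(qx))
    stop("life table contains missing values", call. = FALSE)
  if (any(duplicated(ages)))
    stop("life table has duplicate ages", call. = FALSE)
  if (is.unsorted(ages) || any(diff(ages) != 1L))
    stop("life table ages must be contiguous ascending integers (no gaps)",
         call. = FALSE)
  if (any(qx < 0) || any(qx > 1))
    stop("life table qx values must lie in [0, 1]", call. = FALSE)
  structure(data.frame(age = ages, qx = qx),
            class = c("life_table", "data.frame"))
}

#' Generate a synthetic Gompertz-Makeham life table
#'
#' Produces an annual death-probability table from the Gompertz-Makeham law
#' `qx(age) = min(1, c + a * exp(b * age))`: an age-independent background
#' hazard `c` plus an exponentially increasing senescent component. The
#' defaults give a mortality-doubling time of about 7.4 years and magnitudes
#' comparable to a recent UK national life table; the result is synthetic and
#' stands in for a published table when none is at hand.
#'
#' @param a Baseline senescent hazard scale (>= 0).
#' @param b Log-hazard slope per year of age (>= 0).
#' @param c Age-independent (Makeham) hazard (>= 0).
#' @param max_age Last tabulated age in years (>= 1); lookups beyond it
#'   plateau at `qx(max_age)`.
#' @return A [life_table] covering ages `0:max_age`.
#' @examples
#' lt <- gompertz_life_table()
#' qx_at(lt, 66)
#' @export
gompertz_life_table <- function(a = 3.5e-5, b = 0.094, c = 4e-4,
                                max_age = 110) {
  if (a < 0 || b < 0 || c < 0)
    stop("Gompertz-Makeham parameters must be non-negative", call. = FALSE)
  if (max_age < 1) stop("max_age must be >= 1", call. = FALSE)
  ages <- 0:as.integer(max_age)
  new_life_table(ages, pmin(1, c + a * exp(b * ages)))
}

#' Read a life table from a CSV file
#'
#' Expects a two-column delimited text file with header `age,qx`, one row per
#' integer age. Contiguity, duplicate ages and the `qx` range are validated.
#'
#' @param path Path to the CSV file.
#' @return A validated [life_table].
#' @seealso [write_life_table()]; a bundled synthetic fixture is at
#'   `system.file("extdata/life_table_synthetic_uk.csv", package = "lvohta")`.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path))
    stop("life table file not found: ", path, call. = FALSE)
  df <- tryCatch(
    read.csv(path, colClasses = c("numeric", "numeric")),
    error = function(e) stop("life table parse failure in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!all(c("age", "qx") %in% names(df)))
    stop("life table file must have columns 'age' and 'qx'", call. = FALSE)
  if (any(df$age != round(df$age)))
    stop("life table ages must be integers", call. = FALSE)
  new_life_table(df$age, df$qx)
}

#' Write a life table to CSV
#'
#' @param table A [life_table].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(table, path) {
  stopifnot(inherits(table, "life_table"))
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Annual death probability at a given age
#'
#' Looks up `qx` with plateau extrapolation: ages beyond the table's end
#' return the last tabulated value. Ages below the table's start are an
#' error.
#'
#' @param table A [life_table].
#' @param age Integer age(s) in years.
#' @return Numeric vector of annual death probabilities.
#' @export
qx_at <- function(table, age) {
  stopifnot(inherits(table, "life_table"))
  if (any(age < table$age[1]))
    stop("age below the life table's first tabulated age", call. = FALSE)
  idx <- pmin(age - table$age[1] + 1L, nrow(table))
  table$qx[idx]
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("life table: ages %d-%d, qx range [%.2g, %.2g]\n",
              x$age[1], x$age[nrow(x)], min(x$qx), max(x$qx)))
  invisible(x)
}

#' Randomly perturbed model parameters
#'
#' Property-test input generator: multiplies each scalar parameter of the
#' base case by an independent uniform factor in `[1 - jitter, 1 + jitter]`,
#' clamps probabilities and rates to their valid ranges, perturbs the mRS
#' distributions entrywise and renormalizes them, and re-sorts the perturbed
#' utilities non-increasing so the result always validates. Integer design
#' quantities (starting age, cohort size, cycle count) are left unchanged.
#' Identical seeds give identical output.
#'
#' @param seed Integer seed.
#' @param jitter Relative perturbation fraction in `[0, 0.5]`.
#' @return A validated `lvo_model_params` object.
#' @examples
#' identical(random_params(7, 0.2), random_params(7, 0.2))
#' @export
random_params <- function(seed, jitter = 0.2) {
  if (jitter < 0 || jitter > 0.5)
    stop("jitter must lie in [0, 0.5]", call. = FALSE)
  if (jitter == 0) return(model_params())
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  fac <- function(n = 1L) runif(n, 1 - jitter, 1 + jitter)
  clamp01 <- function(x) pmin(1, pmax(0, x))
  perturb_dist <- function(d) {
    x <- clamp01(as.numeric(d) * fac(7L))
    mrs_distribution(x / sum(x))
  }
  u <- clamp01(default_utilities()$utility_by_state * fac(6L))
  u <- sort(u, decreasing = TRUE)
  model_params(
    p_lvo              = clamp01(0.306 * fac()),
    p_eligible         = clamp01(0.438 * fac()),
    p_missed           = clamp01(0.06 * fac()),
    reduction          = clamp01(0.50 * fac()),
    p_recurrent        = clamp01(0.0284 * fac()),
    mrs_iat            = perturb_dist(default_clinical()$mrs_iat),
    mrs_no_iat         = perturb_dist(default_clinical()$mrs_no_iat),
    acute_by_state     = default_costs()$acute_by_state * fac(7L),
    longterm_by_state  = default_costs()$longterm_by_state * fac(6L),
    tx_iat             = 11728 * fac(),
    tx_no_iat          = 1004 * fac(),
    ai_per_analysis    = 40 * fac(),
    discount_costs     = min(0.2, 0.04 * fac()),
    utility_by_state   = u,
    discount_utilities = min(0.2, 0.015 * fac()),
    wtp_per_qaly       = 25662 * fac(),
    acute_year_fraction = clamp01(90 / 365.25 * fac())
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
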