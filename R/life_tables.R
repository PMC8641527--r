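#' Construct a life table from ages and annual death probabilities
#' @noRd
new_life_table <- function(ages, q_annual) {
  lt <- data.frame(age = as.integer(ages), q_annual = as.numeric(q_annual))
  class(lt) <- c("af_life_table", "data.frame")
  lt
}

#' Load an age-specific mortality table from a delimited text file
#'
#' Expects a header `age,q_annual` and one row per integer age, contiguous
#' and ascending, with `q_annual` the probability of dying within the year
#' at that age. The final age must carry `q_annual = 1` (the terminal age at
#' which the cohort is extinguished).
#'
#' @param path path to a CSV file.
#' @return an `af_life_table` (a data frame with columns `age`, `q_annual`).
#' @export
load_life_table <- function(path) {
  if (!file.exists(path)) stop("life-table file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age", "q_annual") %in% names(df))) {
    stop("life-table file must have columns 'age' and 'q_annual'", call. = FALSE)
  }
  if (nrow(df) < 2) stop("life table needs at least two rows", call. = FALSE)
  if (any(!is.finite(df$age)) || any(df$age != floor(df$age))) {
    stop("life-table ages must be integers", call. = FALSE)
  }
  gaps <- which(diff(df$age) != 1)
  if (length(gaps)) {
    stop("life-table ages must be contiguous and ascending; gap after age ",
         df$age[gaps[1]], call. = FALSE)
  }
  if (any(!is.finite(df$q_annual)) || any(df$q_annual < 0) || any(df$q_annual > 1)) {
    stop("q_annual values must be in [0, 1]", call. = FALSE)
  }
  if (df$q_annual[nrow(df)] != 1) {
    stop("last row must be the terminal age with q_annual = 1", call. = FALSE)
  }
  new_life_table(df$age, df$q_annual)
}

#' Write a life table to CSV
#' @param lt an `af_life_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "af_life_table"))
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a Gompertz-Makeham life table
#'
#' Annual death probability at integer age x is
#' `q(x) = 1 - exp(-(c + a * exp(b * x)))`: an exponentially rising
#' senescent hazard `a * exp(b * x)` plus an age-independent Makeham
#' component `c`. The probability is forced to 1 at `terminal_age`. This is
#' the synthetic stand-in for a national mortality table when none is
#' supplied.
#'
#' @param a baseline senescent hazard (per year), `> 0`.
#' @param b senescence rate (per year), `> 0`.
#' @param c Makeham constant hazard (per year), `>= 0`.
#' @param start_age,terminal_age integer age range covered.
#' @return an `af_life_table`.
#' @examples
#' lt <- gompertz_life_table(a = 5e-4, b = 0.085, c = 0.005)
#' head(lt)
#' @export
gompertz_life_table <- function(a, b, c = 0, start_age = 30, terminal_age = 110) {
  if (!(a > 0) || !(b > 0) || c < 0) {
    stop("need a > 0, b > 0, c >= 0", call. = FALSE)
  }
  if (start_age >= terminal_age) stop("start_age must be below terminal_age", call. = FALSE)
  ages <- seq(floor(start_age), ceiling(terminal_age))
  hazard <- c + a * exp(b * ages)
  if (any(!is.finite(hazard))) {
    stop("hazard overflow at high ages; use a smaller senescence rate b",
         call. = FALSE)
  }
  q <- 1 - exp(-hazard)
  q[length(q)] <- 1
  new_life_table(ages, q)
}

#' Annual death probability at a given age
#'
#' Looks up `q_annual` at `floor(age)`; ages beyond the terminal age
#' return 1.
#'
#' @param lt an `af_life_table`.
#' @param age age in years (may be fractional; vectorised).
#' @return annual death probability.
#' @export
annual_mortality <- function(lt, age) {
  idx <- floor(age) - lt$age[1] + 1
  n <- nrow(lt)
  q <- numeric(length(idx))
  below <- idx < 1
  if (any(below)) {
    stop("age ", min(age), " below the life table's first age ", lt$age[1],
         call. = FALSE)
  }
  above <- idx > n
  q[above] <- 1
  q[!above] <- lt$q_annual[idx[!above]]
  q
}

#' Per-cycle background death probability
#'
#' Converts the annual probability at `floor(age)` to the model's cycle
#' length by constant-hazard rescaling.
#'
#' @param lt an `af_life_table`.
#' @param age age in years (vectorised).
#' @param cycle_length cycle length in years.
#' @return per-cycle death probability.
#' @examples
#' lt <- gompertz_life_table(5e-4, 0.085, 0.005)
#' cycle_mortality(lt, 60, 0.5)
#' @export
cycle_mortality <- function(lt, age, cycle_length = 0.5) {
  to_cycle_probability(annual_mortality(lt, age), 1, cycle_length)
}

#' Calibrate the synthetic life table to a target median survival
#'
#' The national mortality table behind the published analysis is not in the
#' public record, so the default background-mortality input is a
#' Gompertz-Makeham table calibrated such that the full Markov model's
#' untreated no-screening cohort reaches 50% cumulative mortality at the
#' target median survival. Deterministic bisection on the baseline hazard
#' `a`, holding `b` and `c` fixed.
#'
#' @param params an `af_params` object (events, cycle settings).
#' @param target_median target median survival in years from the cohort
#'   start age (base case: 10).
#' @param b,c fixed Gompertz-Makeham shape parameters.
#' @param tol acceptable deviation of the achieved median, in years.
#' @param bracket search interval for `a`.
#' @return list with `a`, `b`, `c`, `achieved_median` and the calibrated
#'   `life_table`.
#' @export
calibrate_median_survival <- function(params, target_median = 10,
                                      b = 0.085, c = 0.005, tol = 0.05,
                                      bracket = c(1e-8, 0.2)) {
  stopifnot(inherits(params, "af_params"))
  start_age <- params$cycle$start_age
  terminal <- params$cycle$max_age
  med_for <- function(a) {
    lt <- gompertz_life_table(a, b, c, start_age = 0, terminal_age = terminal)
    tr <- run_cohort(params, arm = "no_screening", lifetable = lt)
    median_survival(tr)
  }
  lo <- bracket[1]; hi <- bracket[2]
  m_lo <- med_for(lo); m_hi <- med_for(hi)
  # median survival decreases in a
  if (!(m_hi <= target_median && target_median <= m_lo)) {
    stop(sprintf(paste0("calibration target %.2f years outside achievable ",
                        "range [%.2f, %.2f] for a in [%g, %g]"),
                 target_median, m_hi, m_lo, lo, hi), call. = FALSE)
  }
  for (i in seq_len(200)) {
    mid <- sqrt(lo * hi) # hazard scale is multiplicative; bisect in log space
    m_mid <- med_for(mid)
    if (abs(m_mid - target_median) <= tol || (hi / lo) < 1 + 1e-12) break
    if (m_mid > target_median) lo <- mid else hi <- mid
  }
  lt <- gompertz_life_table(mid, b, c, start_age = 0, terminal_age = terminal)
  list(a = mid, b = b, c = c, achieved_median = m_mid, life_table = lt)
}

#' Default calibrated background-mortality table
#'
#' Convenience wrapper: calibrates the Gompertz-Makeham table so the
#' untreated no-screening cohort has the base-case 10-year median survival
#' from the cohort start age.
#'
#' @param params an `af_params` object.
#' @param target_median target median survival in years.
#' @return an `af_life_table`.
#' @export
calibrated_life_table <- function(params, target_median = 10) {
  calibrate_median_survival(params, target_median)$life_table
}

#' Survival curve implied by a life table alone
#'
#' Cumulative survival from `start_age` under background mortality only
#' (no AF event risks). Mostly a diagnostic.
#'
#' @param lt an `af_life_table`.
#' @param start_age first age.
#' @return data frame with `age` and `survival`.
#' @export
lifetable_survival <- function(lt, start_age = lt$age[1]) {
  keep <- lt$age >= floor(start_age)
  q <- lt$q_annual[keep]
  data.frame(age = lt$age[keep], survival = cumprod(c(1, 1 - q))[seq_along(q)])
}

#' @export
print.af_life_table <- function(x, ...) {
  cat(sprintf("Life table: ages %d-%d, q_annual %.5f-%.5f\n",
              min(x$age), max(x$age), min(x$q_annual), max(x$q_annual)))
  invisible(x)
}
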