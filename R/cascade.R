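#' Run the screening decision tree
#'
#' Propagates the national 55+ population through the screening cascade:
#' attendance, AF prevalence, the previously-undiagnosed fraction, and test
#' sensitivity/specificity, yielding the cohort of newly detected AF
#' patients that enters the Markov model, plus the one-time screening cost.
#'
#' Counts are kept fractional through the tree; only the final detected
#' count is rounded (half up), matching the published base case
#' (9,053,294 x 0.5 x 0.01 x 0.7 = 31,686.5 -> 31,687).
#'
#' @param params an `af_params` object (uses its `screening` component).
#' @return an `af_cascade` list: `attended`, `prevalent_af_attending`,
#'   `known_af`, `new_af_true`, `new_af_detected`, `false_positives`,
#'   `costs` (component breakdown), `cost_total`, `cost_per_screened`.
#' @examples
#' cs <- run_cascade(af_parameters())
#' cs$new_af_detected # 31687
#' @export
run_cascade <- function(params) {
  stopifnot(inherits(params, "af_params"))
  sp <- params$screening

  attended <- sp$population * sp$attendance
  prevalent <- attended * sp$prevalence
  known <- prevalent * (1 - sp$unknown_af)
  new_true <- prevalent * sp$unknown_af
  detected <- round_half_up(new_true * sp$sensitivity)
  false_pos <- (attended - prevalent) * (1 - sp$specificity)

  capacity <- sp$n_clinics * sp$persons_per_clinic
  if (attended > capacity) {
    warning(sprintf("attended (%.0f) exceeds clinic capacity (%.0f)",
                    attended, capacity), call. = FALSE)
  }

  res <- list(
    attended = attended,
    prevalent_af_attending = prevalent,
    known_af = known,
    new_af_true = new_true,
    new_af_detected = detected,
    false_positives = false_pos,
    cohort_size = if (identical(sp$cohort_basis, "all_new_af")) {
      round_half_up(new_true)
    } else detected
  )
  res$costs <- screening_cost_total(params, res)
  res$cost_total <- res$costs$total
  res$cost_per_screened <- res$costs$per_screened
  class(res) <- "af_cascade"
  res
}

#' Round half away from zero at the unit
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' One-time screening cost breakdown
#'
#' Devices (one single-lead ECG per clinic at its one-year use cost),
#' screening contacts (per attendee, one third of a health-centre visit by
#' default), and cardiologist confirmation of positive readings. Following
#' the published costing, device specificity is not priced in the base
#' case: confirmations cover detected cases only unless
#' `screening$include_fp_confirmations` is set. Components flagged as
#' international dollars (contact and confirmation visits) are multiplied
#' by `screening$intdollar_to_usd` (default 1, i.e. literal table values).
#'
#' @param params an `af_params` object.
#' @param cascade a cascade result list with `attended`, `new_af_detected`,
#'   `false_positives`.
#' @return list with `devices`, `contacts`, `confirmations`, `total`,
#'   `per_screened`.
#' @export
screening_cost_total <- function(params, cascade) {
  sp <- params$screening
  fx <- sp$intdollar_to_usd
  devices <- sp$n_clinics * sp$device_cost_year
  contacts <- cascade$attended * sp$contact_cost * fx
  n_confirm <- cascade$new_af_detected +
    if (isTRUE(sp$include_fp_confirmations)) cascade$false_positives else 0
  confirmations <- n_confirm * sp$confirmation_cost * fx
  total <- devices + contacts + confirmations
  per_screened <- if (cascade$attended > 0) total / cascade$attended else NA_real_
  list(devices = devices, contacts = contacts, confirmations = confirmations,
       total = total, per_screened = per_screened)
}

#' @export
print.af_cascade <- function(x, ...) {
  cat("AF screening cascade\n")
  cat(sprintf("  attended:              %12s\n", format(round(x$attended), big.mark = ",")))
  cat(sprintf("  prevalent AF attending:%12s\n",
              format(round(x$prevalent_af_attending), big.mark = ",")))
  cat(sprintf("  known AF:              %12s\n", format(round(x$known_af), big.mark = ",")))
  cat(sprintf("  new AF (true):         %12s\n", format(round(x$new_af_true, 1), big.mark = ",")))
  cat(sprintf("  new AF detected:       %12s\n", format(x$new_af_detected, big.mark = ",")))
  cat(sprintf("  false positives:       %12s\n",
              format(round(x$false_positives), big.mark = ",")))
  cat(sprintf("  screening cost total:  $%s (devices $%s, contacts $%s, confirmations $%s)\n",
              format(round(x$cost_total), big.mark = ","),
              format(round(x$costs$devices), big.mark = ","),
              format(round(x$costs$contacts), big.mark = ","),
              format(round(x$costs$confirmations), big.mark = ",")))
  cat(sprintf("  cost per screened:     $%.2f\n", x$cost_per_screened))
  invisible(x)
}
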