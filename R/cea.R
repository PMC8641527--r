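#' Scale per-patient outcomes to cohort totals for one arm
#'
#' Multiplies the per-entrant outcomes by the number of newly detected AF
#' patients and, for the screening arm, adds the one-time screening cost at
#' model start (undiscounted, cycle 0).
#'
#' @param outcomes an `af_outcomes` from [trace_outcomes()].
#' @param cascade an `af_cascade`; `new_af_detected` is the cohort size.
#' @param include_screening add the screening session cost to this arm's
#'   totals (applies to the screening arm).
#' @return an `af_arm_result`: `n`, `per_patient` and `total`, each holding
#'   `discounted`/`undiscounted` lists of `ly`, `qaly`, `cost` and cost
#'   components (`cost_treatment`, `cost_events`, `cost_upkeep`,
#'   `cost_screening`).
#' @export
arm_totals <- function(outcomes, cascade, include_screening = FALSE) {
  stopifnot(inherits(outcomes, "af_outcomes"))
  n <- if (!is.null(cascade$cohort_size)) cascade$cohort_size else cascade$new_af_detected
  if (n <= 0) stop("empty cohort: no newly detected AF patients", call. = FALSE)
  screening_cost <- if (include_screening) cascade$cost_total else 0

  scale_up <- function(tt) {
    out <- lapply(tt, function(v) v * n)
    out$cost_screening <- screening_cost
    out$cost <- out$cost + screening_cost
    out
  }
  total <- list(discounted = scale_up(outcomes$totals$discounted),
                undiscounted = scale_up(outcomes$totals$undiscounted))
  per_patient <- lapply(total, function(tt) lapply(tt, function(v) v / n))
  structure(list(n = n, arm = outcomes$arm, mix = outcomes$mix,
                 per_patient = per_patient, total = total),
            class = "af_arm_result")
}

#' Incremental cost-effectiveness of one arm over another
#'
#' Increments are computed on discounted cohort totals (undiscounted
#' reported alongside). The ICER is delta-cost over delta-QALY when the
#' latter is meaningfully positive; quadrants with negative increments are
#' classified as dominance instead.
#'
#' @param case an `af_arm_result` for the intervention (screening) arm.
#' @param base an `af_arm_result` for the comparator (no screening) arm.
#' @param wtp willingness-to-pay threshold (US$/QALY) for the net monetary
#'   benefit.
#' @return an `af_ce_result`: `delta` (cohort and per-patient increments,
#'   discounted and undiscounted), `icer`, `icer_undiscounted`,
#'   `dominance` (`"icer"`, `"dominant"`, `"dominated"` or `"undefined"`),
#'   `nmb`, `wtp`, `n`.
#' @export
icer <- function(case, base, wtp = 2000) {
  stopifnot(inherits(case, "af_arm_result"), inherits(base, "af_arm_result"))
  if (case$n != base$n) stop("arms have different cohort sizes", call. = FALSE)

  delta_of <- function(which) {
    list(qaly = case$total[[which]]$qaly - base$total[[which]]$qaly,
         ly = case$total[[which]]$ly - base$total[[which]]$ly,
         cost = case$total[[which]]$cost - base$total[[which]]$cost)
  }
  d <- delta_of("discounted")
  du <- delta_of("undiscounted")
  per_patient <- lapply(d, function(v) v / case$n)

  ratio <- function(dc, dq) {
    if (abs(dq) < 1e-9) return(NA_real_)
    dc / dq
  }
  dominance <-
    if (abs(d$qaly) < 1e-9) "undefined"
    else if (d$qaly > 0 && d$cost <= 0) "dominant"
    else if (d$qaly < 0 && d$cost >= 0) "dominated"
    else "icer"
  structure(list(
    delta = list(discounted = d, undiscounted = du, per_patient = per_patient),
    icer = if (dominance == "icer") ratio(d$cost, d$qaly) else NA_real_,
    icer_undiscounted = if (dominance == "icer") ratio(du$cost, du$qaly) else NA_real_,
    dominance = dominance,
    nmb = nmb_value(d$qaly / case$n, d$cost / case$n, wtp),
    wtp = wtp, n = case$n
  ), class = "af_ce_result")
}

#' Net monetary benefit
#'
#' `NMB = wtp * delta_QALY - delta_cost`; non-negative NMB means the
#' intervention is cost-effective at that willingness to pay.
#'
#' @param delta_qaly,delta_cost increments (any consistent scale).
#' @param wtp willingness-to-pay threshold, `> 0`.
#' @return NMB on the same scale as the inputs.
#' @export
nmb_value <- function(delta_qaly, delta_cost, wtp) {
  if (wtp <= 0) stop("wtp must be positive", call. = FALSE)
  wtp * delta_qaly - delta_cost
}

#' Run the full cost-effectiveness analysis
#'
#' Decision-tree cascade, lifetime Markov traces for both arms, outcome
#' aggregation and incremental economics for a given treatment mix. This is
#' the package's central entry point.
#'
#' @param params an `af_params` object.
#' @param lifetable an `af_life_table`; if `NULL`, the Gompertz-Makeham
#'   table calibrated to a 10-year untreated median survival is built.
#' @param mix NOAC fraction of the treatment mix (1 = all NOAC, 0 = all
#'   warfarin); defaults to `params$mix$frac_noac`.
#' @return an `af_cea` object: `cascade`, `traces`, `arms` (screening and
#'   no-screening `af_arm_result`s), `ce` (the `af_ce_result`),
#'   `median_survival` per arm, plus the inputs used.
#' @examples
#' \donttest{
#' p <- af_parameters()
#' lt <- calibrated_life_table(p)
#' res <- run_cea(p, lt)
#' summary(res)
#' }
#' @export
run_cea <- function(params, lifetable = NULL, mix = params$mix$frac_noac) {
  stopifnot(inherits(params, "af_params"))
  if (is.null(lifetable)) lifetable <- calibrated_life_table(params)
  cascade <- run_cascade(params)

  tr_s <- run_cohort(params, "screening", lifetable)
  tr_n <- run_cohort(params, "no_screening", lifetable)
  out_s <- trace_outcomes(tr_s, params, mix)
  out_n <- trace_outcomes(tr_n, params, mix)

  arm_s <- arm_totals(out_s, cascade,
                      include_screening = isTRUE(params$include_screening_cost_in_icer))
  arm_n <- arm_totals(out_n, cascade, include_screening = FALSE)
  ce <- icer(arm_s, arm_n, wtp = params$wtp)

  structure(list(
    params = params, lifetable = lifetable, mix = mix,
    cascade = cascade,
    traces = list(screening = tr_s, no_screening = tr_n),
    outcomes = list(screening = out_s, no_screening = out_n),
    arms = list(screening = arm_s, no_screening = arm_n),
    ce = ce,
    median_survival = c(screening = median_survival(tr_s),
                        no_screening = median_survival(tr_n))
  ), class = "af_cea")
}

#' Headline results table for one or more treatment mixes
#'
#' Builds the lifetime-results report: cohort QALYs, life years and costs
#' for the on-treatment (screening) and no-treatment (no-screening) arms,
#' the increment row, and the ICER, in discounted and undiscounted panels.
#'
#' @param params an `af_params` object.
#' @param lifetable an `af_life_table` (calibrated if `NULL`).
#' @param mixes named numeric vector of NOAC fractions to report.
#' @return an `af_report` data frame with columns `mix`, `discounting`,
#'   `row`, `qalys`, `lys`, `costs`, `icer`.
#' @export
table5_report <- function(params, lifetable = NULL,
                          mixes = c(noac = 1)) {
  if (is.null(lifetable)) lifetable <- calibrated_life_table(params)
  rows <- list()
  for (mname in names(mixes)) {
    cea <- run_cea(params, lifetable, mix = mixes[[mname]])
    for (disc in c("discounted", "undiscounted")) {
      s <- cea$arms$screening$total[[disc]]
      b <- cea$arms$no_screening$total[[disc]]
      d <- cea$ce$delta[[disc]]
      icer_val <- if (disc == "discounted") cea$ce$icer else cea$ce$icer_undiscounted
      rows[[length(rows) + 1]] <- data.frame(
        mix = mname, discounting = disc,
        row = c("on_treatment", "no_treatment", "delta"),
        qalys = c(s$qaly, b$qaly, d$qaly),
        lys = c(s$ly, b$ly, d$ly),
        costs = c(s$cost, b$cost, d$cost),
        icer = c(NA, NA, icer_val)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("af_report", "data.frame")
  out
}

#' Write a results report as CSV or JSON
#' @param report an `af_report` from [table5_report()].
#' @param path output path; format chosen by extension (.csv or .json).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  }
  invisible(path)
}

#' @export
print.af_ce_result <- function(x, ...) {
  d <- x$delta$discounted
  pp <- x$delta$per_patient
  cat("Incremental cost-effectiveness (discounted)\n")
  cat(sprintf("  dQALY %s  dLY %s  dCost $%s  (cohort N = %s)\n",
              format(round(d$qaly), big.mark = ","),
              format(round(d$ly), big.mark = ","),
              format(round(d$cost), big.mark = ","),
              format(x$n, big.mark = ",")))
  cat(sprintf("  per patient: %.3f QALY, $%.0f\n", pp$qaly, pp$cost))
  if (x$dominance == "icer") {
    cat(sprintf("  ICER: $%s/QALY (undiscounted $%s/QALY)\n",
                format(round(x$icer), big.mark = ","),
                format(round(x$icer_undiscounted), big.mark = ",")))
  } else {
    cat(sprintf("  dominance: %s\n", x$dominance))
  }
  cat(sprintf("  NMB at WTP $%s/QALY: $%.0f per patient (%scost-effective)\n",
              format(x$wtp, big.mark = ","), x$nmb,
              if (x$nmb >= 0) "" else "not "))
  invisible(x)
}

#' @export
print.af_cea <- function(x, ...) {
  cat(sprintf("AF screening cost-effectiveness analysis (%.0f%% NOAC)\n",
              100 * x$mix))
  cat(sprintf("  newly detected AF patients: %s\n",
              format(x$cascade$new_af_detected, big.mark = ",")))
  cat(sprintf("  median survival: %.2f years (screening) vs %.2f years (no screening)\n",
              x$median_survival["screening"], x$median_survival["no_screening"]))
  print(x$ce)
  invisible(x)
}

#' @export
summary.af_cea <- function(object, ...) {
  x <- object
  print(x)
  cat("\nCohort totals (discounted):\n")
  for (a in c("screening", "no_screening")) {
    t <- x$arms[[a]]$total$discounted
    cat(sprintf("  %-12s QALYs %10s  LYs %10s  costs $%14s  (treatment %2.0f%%)\n",
                a,
                format(round(t$qaly), big.mark = ","),
                format(round(t$ly), big.mark = ","),
                format(round(t$cost), big.mark = ","),
                100 * t$cost_treatment / t$cost))
  }
  invisible(x)
}
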