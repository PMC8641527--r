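#' Model state space
#'
#' Ordered health states of the Markov model. `ACUTE_STROKE` and
#' `ACUTE_BLEED` are single-cycle tunnel states; the four `DEAD_*` states
#' are absorbing.
#'
#' @return character vector of state names.
#' @export
af_states <- function() {
  c("AF", "ACUTE_STROKE", "POST_STROKE", "ACUTE_BLEED",
    "DEAD_STROKE_ACUTE", "DEAD_POST_STROKE", "DEAD_BLEED", "DEAD_AGE")
}

#' Arm specification
#'
#' In the screening arm all newly detected AF patients initiate oral
#' anticoagulation at model start; in the no-screening arm AF goes
#' undetected and anticoagulation starts only after a first stroke. Both
#' arms treat stroke survivors, with persistence measured from stroke
#' onset.
#'
#' @param arm `"screening"` or `"no_screening"`.
#' @return an `af_arm` list with `arm`, `treat_from_start`,
#'   `treat_after_stroke`.
#' @export
make_arm <- function(arm = c("screening", "no_screening")) {
  arm <- match.arg(arm)
  structure(list(arm = arm,
                 treat_from_start = arm == "screening",
                 treat_after_stroke = TRUE),
            class = "af_arm")
}

#' On-treatment fraction of a state's occupants during a cycle
#'
#' Therapy persistence is 70% during the first 6-month cycle on therapy and
#' 60% thereafter. For the AF state the clock starts at model entry
#' (screening arm) or never (no-screening arm); for stroke survivors it
#' starts at stroke onset, so the one-cycle acute-stroke tunnel carries the
#' first-cycle persistence and the post-stroke state the later one. Bleed
#' tunnel occupants are off treatment for that cycle.
#'
#' @param cycle_index 1-based cycle number since model start.
#' @param arm an `af_arm` or arm name.
#' @param persistence the `persistence` component of an `af_params`.
#' @param state state name (default `"AF"`).
#' @return fraction in `[0, 1]`.
#' @export
on_treatment_fraction <- function(cycle_index, arm, persistence, state = "AF") {
  if (is.character(arm)) arm <- make_arm(arm)
  stopifnot(cycle_index >= 1)
  switch(state,
    AF = if (arm$treat_from_start) {
      if (cycle_index == 1) persistence$persist_first_cycle else persistence$persist_later
    } else 0,
    ACUTE_STROKE = if (arm$treat_after_stroke) persistence$persist_first_cycle else 0,
    POST_STROKE = if (arm$treat_after_stroke) persistence$persist_later else 0,
    0)
}

#' Per-cycle dynamic quantities for a cohort run
#'
#' Precomputes, for every cycle, the blended (treated/untreated) event
#' probabilities and background mortality used by both the cohort engine
#' and the transition-matrix builder.
#' @noRd
cycle_schedule <- function(params, arm, lifetable, n_cycles) {
  if (is.character(arm)) arm <- make_arm(arm)
  cy <- params$cycle
  e <- params$events
  m <- effective_multipliers(params$effect)
  pe <- params$persistence

  k <- seq_len(n_cycles) - 1L # 0-based cycle index
  age <- cy$start_age + cy$cycle_length * k
  q <- cycle_mortality(lifetable, age, cy$cycle_length)

  f_af <- if (arm$treat_from_start) {
    ifelse(k == 0, pe$persist_first_cycle, pe$persist_later)
  } else rep(0, n_cycles)
  f_as <- if (arm$treat_after_stroke) pe$persist_first_cycle else 0
  f_ps <- if (arm$treat_after_stroke) pe$persist_later else 0

  blend <- function(p, mult, f) p * (1 - f + f * mult)

  p_stroke <- blend(e$p_stroke, m$m_stroke, f_af)
  p_bleed <- blend(e$p_major_bleed, m$m_bleed, f_af)
  if (isTRUE(params$options$conditional_acute_death)) {
    p_fs <- p_stroke * e$p_stroke_acute_death
    p_fb <- p_bleed * e$p_bleed_acute_death
  } else {
    p_fs <- blend(e$p_stroke_acute_death, m$m_stroke, f_af)
    p_fb <- blend(e$p_bleed_acute_death, m$m_bleed, f_af)
  }
  probs <- c(p_stroke, p_bleed, p_fs, p_fb)
  if (any(probs < 0) || any(probs > 1) || any(p_fs > p_stroke) ||
      any(p_fb > p_bleed)) {
    stop("model-consistency error in state AF: blended event probabilities ",
         "outside [0, 1]", call. = FALSE)
  }
  if (any(p_stroke + p_bleed > 1)) {
    stop("model-consistency error in state AF: event probabilities ",
         "over-subscribed (p_stroke + p_major_bleed > 1)", call. = FALSE)
  }

  list(
    arm = arm, n_cycles = n_cycles, age = age, q = q,
    f_af = f_af, f_as = f_as, f_ps = f_ps,
    p_nf_stroke = p_stroke - p_fs, p_fatal_stroke = p_fs,
    p_nf_bleed = p_bleed - p_fb, p_fatal_bleed = p_fb,
    p_psd = e$p_post_stroke_death,
    # certain death at the terminal age stays certain for the treated too
    q_af = ifelse(q >= 1, 1, blend(q, m$m_mortality, f_af)),
    q_as = ifelse(q >= 1, 1, blend(q, m$m_mortality, f_as)),
    q_ps = ifelse(q >= 1, 1, blend(q, m$m_mortality, f_ps)),
    q_ab = q,
    residual_af = 1 - p_stroke - p_bleed,
    bleed_tunnel = isTRUE(params$options$bleed_tunnel)
  )
}

#' Build the transition matrix for one cycle
#'
#' Row-stochastic matrix over [af_states()] for a given age and cycle.
#' Competing risks within a cycle: event probabilities are applied jointly,
#' with background (age) mortality multiplied into the residual; the
#' `DEAD_*` rows are identity rows. Used directly by the individual-level
#' microsimulation and as the cross-check for the vectorised cohort engine.
#'
#' @param params an `af_params` object.
#' @param arm an `af_arm` or arm name.
#' @param lifetable an `af_life_table`.
#' @param cycle_index 1-based cycle number.
#' @return 8 x 8 matrix with dimnames from [af_states()].
#' @export
build_transition_matrix <- function(params, arm, lifetable, cycle_index) {
  sch <- cycle_schedule(params, arm, lifetable, cycle_index)
  transition_from_schedule(sch, cycle_index)
}

#' Propagate the cohort through the Markov model
#'
#' Starts the full cohort in the AF state at the start age and iterates in
#' 6-month cycles until (numerical) extinction or the maximum age. Row `k`
#' of the occupancy matrix is the state distribution at the start of cycle
#' `k` (0-based, so row 0 is the initial distribution); event entries
#' recorded at row `k` occurred during cycle `k - 1`.
#'
#' @param params an `af_params` object.
#' @param arm `"screening"`, `"no_screening"` or an `af_arm`.
#' @param lifetable an `af_life_table` covering the cohort's age range.
#' @return an `af_trace`: list with `occupancy` (cycles x 8), `entries`
#'   (new nonfatal/fatal strokes and bleeds per cycle), `age`, `living`,
#'   and the `arm`.
#' @export
run_cohort <- function(params, arm = "screening", lifetable) {
  stopifnot(inherits(params, "af_params"))
  cy <- params$cycle
  # a few cycles past the terminal age so the tunnel states drain after q hits 1
  n_max <- floor((cy$max_age - cy$start_age) / cy$cycle_length) + 4L
  sch <- cycle_schedule(params, arm, lifetable, n_max)

  occ <- matrix(0, n_max, 8, dimnames = list(NULL, af_states()))
  ent <- matrix(0, n_max, 4,
                dimnames = list(NULL, c("nonfatal_stroke", "fatal_stroke",
                                        "nonfatal_bleed", "fatal_bleed")))
  occ[1, 1] <- 1
  last <- n_max
  for (k in seq_len(n_max - 1L)) {
    af <- occ[k, 1]; as_ <- occ[k, 2]; ps <- occ[k, 3]; ab <- occ[k, 4]
    res <- sch$residual_af[k]
    surv_as <- (1 - sch$p_psd)
    nfs <- af * sch$p_nf_stroke[k]
    fs <- af * sch$p_fatal_stroke[k]
    nfb <- af * sch$p_nf_bleed[k]
    fb <- af * sch$p_fatal_bleed[k]

    stay_af <- af * res * (1 - sch$q_af[k]) + ab * (1 - sch$q_ab[k])
    if (!sch$bleed_tunnel) stay_af <- stay_af + nfb

    occ[k + 1, 1] <- stay_af
    occ[k + 1, 2] <- nfs
    occ[k + 1, 3] <- as_ * surv_as * (1 - sch$q_as[k]) +
      ps * surv_as * (1 - sch$q_ps[k])
    occ[k + 1, 4] <- if (sch$bleed_tunnel) nfb else 0
    occ[k + 1, 5] <- occ[k, 5] + fs
    occ[k + 1, 6] <- occ[k, 6] + (as_ + ps) * sch$p_psd
    occ[k + 1, 7] <- occ[k, 7] + fb
    occ[k + 1, 8] <- occ[k, 8] + af * res * sch$q_af[k] +
      as_ * surv_as * sch$q_as[k] + ps * surv_as * sch$q_ps[k] +
      ab * sch$q_ab[k]
    ent[k + 1, ] <- c(nfs, fs, nfb, fb)

    if (sum(occ[k + 1, 1:4]) < 1e-8) {
      last <- k + 1L
      break
    }
  }
  if (last == n_max && sum(occ[n_max, 1:4]) >= 1e-8) {
    warning(sprintf("cohort not extinct at max_age %g; residual living mass %.3g",
                    cy$max_age, sum(occ[n_max, 1:4])), call. = FALSE)
  }
  idx <- seq_len(last)
  structure(list(
    occupancy = occ[idx, , drop = FALSE],
    entries = ent[idx, , drop = FALSE],
    age = sch$age[idx],
    living = rowSums(occ[idx, 1:4, drop = FALSE]),
    arm = sch$arm,
    f_af = sch$f_af[idx], f_as = sch$f_as, f_ps = sch$f_ps,
    cycle_length = cy$cycle_length
  ), class = "af_trace")
}

#' Per-cycle and total outcomes of a cohort trace
#'
#' Values per model entrant. Life years count living occupancy at the start
#' of each cycle times the cycle length; QALYs weight each state's
#' occupancy by its utility. Costs comprise event costs at entry (acute
#' stroke, fatal stroke, major bleed, fatal bleed), post-stroke upkeep per
#' cycle, and anticoagulation costs (drug, plus INR monitoring for the
#' warfarin fraction) on the treated occupancy. Discounting is annual at
#' the configured rate, applied per half-year cycle; the first cycle is
#' undiscounted. Optional half-cycle correction halves the first cycle's
#' state-membership quantities.
#'
#' @param trace an `af_trace` from [run_cohort()].
#' @param params an `af_params` object.
#' @param mix NOAC fraction of the treatment mix; defaults to
#'   `params$mix$frac_noac`.
#' @param per_cycle build the per-cycle data frame (disable inside tight
#'   Monte Carlo loops where only totals are needed).
#' @return an `af_outcomes` list: `per_cycle` data frame (or `NULL`) and
#'   `totals` (lists `discounted` and `undiscounted`, each with `ly`,
#'   `qaly`, `cost`, `cost_treatment`, `cost_events`, `cost_upkeep`).
#' @export
trace_outcomes <- function(trace, params, mix = params$mix$frac_noac,
                           per_cycle = TRUE) {
  stopifnot(inherits(trace, "af_trace"))
  u <- params$utilities
  co <- params$costs
  cy <- params$cycle
  occ <- trace$occupancy
  ent <- trace$entries
  n <- nrow(occ)
  k <- seq_len(n) - 1L

  len <- trace$cycle_length
  disc <- (1 + cy$discount_rate)^(-len * k)
  w <- rep(1, n)
  if (isTRUE(params$options$half_cycle_correction)) w[1] <- 0.5

  ly <- trace$living * len * w
  qaly <- (occ[, "AF"] * u$u_af +
           occ[, "ACUTE_STROKE"] * u$u_acute_stroke +
           occ[, "POST_STROKE"] * u$u_post_stroke +
           occ[, "ACUTE_BLEED"] * u$u_major_bleed) * len * w
  if (!isTRUE(params$options$bleed_tunnel)) {
    qaly <- qaly - ent[, "nonfatal_bleed"] * u$d_bleed * len
  }

  drug <- mix * co$c_noac + (1 - mix) * (co$c_warfarin + co$c_inr)
  treated <- occ[, "AF"] * trace$f_af +
    occ[, "ACUTE_STROKE"] * trace$f_as +
    occ[, "POST_STROKE"] * trace$f_ps
  cost_treatment <- treated * drug * w
  cost_events <- ent[, "nonfatal_stroke"] * co$c_acute_stroke +
    ent[, "fatal_stroke"] * co$c_stroke_death +
    ent[, "nonfatal_bleed"] * co$c_major_bleed +
    ent[, "fatal_bleed"] * co$c_bleed_death
  cost_upkeep <- occ[, "POST_STROKE"] * co$c_post_stroke * w
  cost <- cost_treatment + cost_events + cost_upkeep

  pc <- if (per_cycle) data.frame(
    cycle = k, age = trace$age, living = trace$living,
    ly = ly, qaly = qaly, cost = cost,
    cost_treatment = cost_treatment, cost_events = cost_events,
    cost_upkeep = cost_upkeep, discount = disc
  ) else NULL
  tot <- function(d) list(
    ly = sum(ly * d), qaly = sum(qaly * d), cost = sum(cost * d),
    cost_treatment = sum(cost_treatment * d),
    cost_events = sum(cost_events * d),
    cost_upkeep = sum(cost_upkeep * d)
  )
  structure(list(
    per_cycle = pc,
    totals = list(discounted = tot(disc), undiscounted = tot(rep(1, n))),
    mix = mix, arm = trace$arm$arm
  ), class = "af_outcomes")
}

#' Median survival of a cohort trace
#'
#' Years from model entry until the living fraction crosses 0.5, linearly
#' interpolated between cycles.
#'
#' @param trace an `af_trace`.
#' @return years; `NA` with a warning if the trace never crosses 0.5.
#' @export
median_survival <- function(trace) {
  s <- trace$living
  len <- trace$cycle_length
  if (s[length(s)] >= 0.5) {
    warning("living fraction never falls below 0.5; median survival undefined",
            call. = FALSE)
    return(NA_real_)
  }
  i <- which(s < 0.5)[1] # first row strictly below half
  if (i == 1) return(0)
  frac <- (s[i - 1] - 0.5) / (s[i - 1] - s[i])
  len * (i - 2 + frac)
}

#' Export a cohort trace to CSV
#'
#' One row per cycle: cycle index, age, one column per state, event
#' entries, and (if `params` is given) per-cycle LYs, QALYs and costs with
#' their discounted variants.
#'
#' @param trace an `af_trace`.
#' @param path output path.
#' @param params optionally, an `af_params` to append outcome columns.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, params = NULL) {
  df <- data.frame(cycle = seq_len(nrow(trace$occupancy)) - 1L,
                   age = trace$age, trace$occupancy, trace$entries,
                   living = trace$living, check.names = FALSE)
  if (!is.null(params)) {
    oc <- trace_outcomes(trace, params)$per_cycle
    df <- cbind(df, oc[, c("ly", "qaly", "cost", "discount")])
    df$ly_disc <- df$ly * df$discount
    df$qaly_disc <- df$qaly * df$discount
    df$cost_disc <- df$cost * df$discount
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.af_trace <- function(x, ...) {
  cat(sprintf("Markov cohort trace (%s arm): %d cycles, ages %.1f-%.1f\n",
              x$arm$arm, nrow(x$occupancy), min(x$age), max(x$age)))
  ms <- suppressWarnings(median_survival(x))
  if (!is.na(ms)) cat(sprintf("  median survival: %.2f years\n", ms))
  cat(sprintf("  final living fraction: %.2e\n", x$living[length(x$living)]))
  invisible(x)
}
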