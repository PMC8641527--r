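#' Default model parameters
#'
#' Builds the base-case parameter bundle for the AF screening evaluation:
#' a one-time single-lead-ECG screening session in the Nigerian population
#' aged 55 and over, followed by lifetime oral anticoagulation in newly
#' detected AF patients, evaluated against no screening (anticoagulation
#' only after a first stroke).
#'
#' All values are the published base case: per-6-month event probabilities,
#' treatment relative risks, health-state utilities, 2018 US$/int$ costs,
#' therapy persistence (70% in the first cycle, 60% thereafter), a 4% annual
#' discount rate and a $2,000/QALY willingness-to-pay threshold.
#'
#' @param ... named overrides, e.g. `wtp = 1000` or
#'   `events = list(p_stroke = 0.02)`. Nested lists are merged into the
#'   defaults; unknown keys are an error.
#' @return An object of class `af_params`: a validated named list with
#'   components `cycle`, `events`, `effect`, `utilities`, `costs`,
#'   `persistence`, `mix`, `screening`, `wtp`,
#'   `include_screening_cost_in_icer`, `options` and `psa`.
#' @examples
#' p <- af_parameters()
#' p$events$p_stroke
#' p2 <- af_parameters(mix = list(frac_noac = 0))  # 100% warfarin
#' @export
af_parameters <- function(...) {
  params <- default_parameter_list()
  overrides <- list(...)
  if (length(overrides)) {
    params <- merge_parameters(params, overrides)
  }
  if (is.null(params$psa)) {
    params$psa <- default_psa_distributions(params)
  }
  params <- validate_parameters(params)
  class(params) <- "af_params"
  params
}

default_parameter_list <- function() {
  list(
    cycle = list(
      cycle_length = 0.5,   # years; 6-month Markov cycles
      discount_rate = 0.04, # annual, applied to both costs and effects
      start_age = 55,
      max_age = 110
    ),
    # per-6-month event probabilities in untreated AF
    events = list(
      p_stroke = 0.0108,            # ischemic stroke + intracranial haemorrhage
      p_stroke_acute_death = 0.0023,
      p_post_stroke_death = 0.1751, # per cycle, lifelong after stroke
      p_major_bleed = 0.0013,       # extracranial (GI) major bleeding
      p_bleed_acute_death = 0.0001
    ),
    # printed relative-risk triplet for oral anticoagulation vs none;
    # mapping_mode resolves which event each multiplier attaches to
    effect = list(
      rr_stroke = 0.38,
      rr_bleed = 0.74,
      rr_mortality = 2.40,
      mapping_mode = "clinically_coherent"
    ),
    # annual utilities; bleeding disutility applies over one 6-month cycle
    utilities = list(
      u_af = 0.8430,
      u_acute_stroke = 0.3280,
      u_post_stroke = 0.5490,
      u_major_bleed = 0.8140,
      d_bleed = 0.029
    ),
    # per-6-month amounts, 2018 US$/int$
    costs = list(
      c_acute_stroke = 938,
      c_post_stroke = 6,
      c_stroke_death = 1126,
      c_major_bleed = 195,
      c_bleed_death = 778,
      c_noac = 448,
      c_warfarin = 17,
      c_inr = 30
    ),
    persistence = list(
      persist_first_cycle = 0.70,
      persist_later = 0.60
    ),
    mix = list(frac_noac = 1.0),
    screening = list(
      population = 9053294,     # Nigerians aged >= 55
      attendance = 0.50,
      prevalence = 0.01,
      unknown_af = 0.70,        # share of prevalent AF previously undiagnosed
      sensitivity = 1.00,       # single-lead ECG device
      specificity = 0.959,
      n_clinics = 1000,
      device_cost_year = 275,   # US$ per device-year
      persons_per_clinic = 4500,
      contact_cost = 5.20 / 3,  # one third of an int$5.20 health-centre visit
      confirmation_cost = 5.20, # cardiologist confirmation per case reviewed
      include_fp_confirmations = FALSE,
      intdollar_to_usd = 1.0,
      # "detected": modelled cohort is the sensitivity-adjusted detected
      # count; "all_new_af": cohort is every new AF case, with test misses
      # reflected in the on-treatment fraction (pulse-palpation scenario)
      cohort_basis = "detected"
    ),
    wtp = 2000, # US$/QALY, approximately Nigeria's 2018 GDP per capita
    include_screening_cost_in_icer = TRUE,
    options = list(
      half_cycle_correction = FALSE,
      conditional_acute_death = FALSE, # read p_stroke_acute_death as P(fatal | stroke)
      bleed_tunnel = TRUE,
      cost_distribution = "beta",      # "gamma" available for PSA cost draws
      stroke_mild_fraction = 0.67      # severity split carried as metadata only
    ),
    psa = NULL
  )
}

#' Merge user overrides into a parameter list, rejecting unknown keys
#' @noRd
merge_parameters <- function(base, overrides, path = "") {
  if (!is.list(overrides)) {
    stop("overrides must be a named list at '", path, "'", call. = FALSE)
  }
  nms <- names(overrides)
  if (is.null(nms) || any(nms == "")) {
    stop("all override entries must be named at '", path, "'", call. = FALSE)
  }
  for (nm in nms) {
    full <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base)) {
      stop("unknown parameter key: '", full, "'", call. = FALSE)
    }
    if (is.list(base[[nm]]) && nm != "psa") {
      base[[nm]] <- merge_parameters(base[[nm]], overrides[[nm]], full)
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

#' Validate a parameter bundle
#'
#' Checks every structural invariant of the model inputs and reports all
#' violations at once.
#'
#' @param params a parameter list as built by [af_parameters()].
#' @return the validated object, invisibly classed as `af_params`.
#' @export
validate_parameters <- function(params) {
  bad <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) bad <<- c(bad, msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  prob <- function(x) num1(x) && x >= 0 && x <= 1

  cy <- params$cycle
  chk(num1(cy$cycle_length) && cy$cycle_length > 0 && cy$cycle_length <= 1,
      "cycle.cycle_length must be in (0, 1]")
  chk(num1(cy$discount_rate) && cy$discount_rate >= 0 && cy$discount_rate < 1,
      "cycle.discount_rate must be in [0, 1)")
  chk(num1(cy$start_age) && num1(cy$max_age) && cy$start_age < cy$max_age,
      "cycle.start_age must be below cycle.max_age")

  ev <- params$events
  for (nm in names(ev)) {
    chk(prob(ev[[nm]]), paste0("events.", nm, " must be a probability in [0, 1]"))
  }
  if (prob(ev$p_stroke) && prob(ev$p_stroke_acute_death) &&
      !isTRUE(params$options$conditional_acute_death)) {
    chk(ev$p_stroke_acute_death <= ev$p_stroke,
        "events.p_stroke_acute_death must not exceed events.p_stroke")
  }
  if (prob(ev$p_major_bleed) && prob(ev$p_bleed_acute_death) &&
      !isTRUE(params$options$conditional_acute_death)) {
    chk(ev$p_bleed_acute_death <= ev$p_major_bleed,
        "events.p_bleed_acute_death must not exceed events.p_major_bleed")
  }

  ef <- params$effect
  for (nm in c("rr_stroke", "rr_bleed", "rr_mortality")) {
    chk(num1(ef[[nm]]) && ef[[nm]] > 0, paste0("effect.", nm, " must be > 0"))
  }
  chk(ef$mapping_mode %in% c("clinically_coherent", "literal_table"),
      "effect.mapping_mode must be 'clinically_coherent' or 'literal_table'")

  ut <- params$utilities
  for (nm in c("u_af", "u_acute_stroke", "u_post_stroke", "u_major_bleed")) {
    chk(prob(ut[[nm]]), paste0("utilities.", nm, " must be in [0, 1]"))
  }
  chk(num1(ut$d_bleed) && ut$d_bleed >= 0 && ut$d_bleed <= 1,
      "utilities.d_bleed must be in [0, 1]")

  co <- params$costs
  for (nm in names(co)) {
    chk(num1(co[[nm]]) && co[[nm]] >= 0, paste0("costs.", nm, " must be >= 0"))
  }

  pe <- params$persistence
  chk(prob(pe$persist_first_cycle), "persistence.persist_first_cycle must be in [0, 1]")
  chk(prob(pe$persist_later), "persistence.persist_later must be in [0, 1]")
  if (prob(pe$persist_first_cycle) && prob(pe$persist_later) &&
      pe$persist_later > pe$persist_first_cycle) {
    warning("persistence.persist_later exceeds persist_first_cycle; ",
            "patients would resume therapy over time", call. = FALSE)
  }

  chk(prob(params$mix$frac_noac), "mix.frac_noac must be in [0, 1]")

  sc <- params$screening
  chk(num1(sc$population) && sc$population >= 0, "screening.population must be >= 0")
  for (nm in c("attendance", "prevalence", "unknown_af", "sensitivity", "specificity")) {
    chk(prob(sc[[nm]]), paste0("screening.", nm, " must be in [0, 1]"))
  }
  for (nm in c("n_clinics", "device_cost_year", "persons_per_clinic",
               "contact_cost", "confirmation_cost", "intdollar_to_usd")) {
    chk(num1(sc[[nm]]) && sc[[nm]] >= 0, paste0("screening.", nm, " must be >= 0"))
  }
  chk(sc$cohort_basis %in% c("detected", "all_new_af"),
      "screening.cohort_basis must be 'detected' or 'all_new_af'")

  chk(num1(params$wtp) && params$wtp > 0, "wtp must be > 0")

  if (length(bad)) {
    stop("invalid parameters:\n  - ", paste(bad, collapse = "\n  - "), call. = FALSE)
  }
  class(params) <- "af_params"
  invisible(params)
}

#' Load model parameters from a YAML configuration file
#'
#' Reads a YAML file whose top-level keys are a subset of the parameter
#' bundle (`cycle`, `events`, `effect`, `utilities`, `costs`, `persistence`,
#' `mix`, `screening`, `wtp`, `include_screening_cost_in_icer`, `options`),
#' merges it into the built-in base case and validates the result. With
#' `path = NULL` the base case itself is returned.
#'
#' @param path path to a YAML file, or `NULL` for the built-in defaults.
#' @return an `af_params` object.
#' @seealso [write_parameters()] to dump the base case as a template.
#' @export
load_parameters <- function(path = NULL) {
  if (is.null(path)) {
    return(af_parameters())
  }
  if (!file.exists(path)) {
    stop("parameter file not found: ", path, call. = FALSE)
  }
  cfg <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop("failed to parse '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(cfg)) cfg <- list()
  do.call(af_parameters, cfg)
}

#' Write a parameter bundle to a YAML file
#'
#' @param params an `af_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "af_params"))
  out <- unclass(params)
  out$psa <- NULL # distributions are derived, not configured
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Convert an event probability between time horizons
#'
#' Constant-hazard rescaling: a probability `p` observed over `from_horizon`
#' years becomes `1 - (1 - p)^(to_horizon / from_horizon)` over
#' `to_horizon` years. Used to turn annual literature rates into 6-month
#' cycle probabilities.
#'
#' @param p probability in `[0, 1]`.
#' @param from_horizon,to_horizon horizons in years, both `> 0`.
#' @return the rescaled probability.
#' @examples
#' to_cycle_probability(0.0215, 1, 0.5) # ~0.0108, the 6-month stroke risk
#' @export
to_cycle_probability <- function(p, from_horizon, to_horizon) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p must be in [0, 1]", call. = FALSE)
  }
  if (from_horizon <= 0 || to_horizon <= 0) {
    stop("horizons must be positive", call. = FALSE)
  }
  1 - (1 - p)^(to_horizon / from_horizon)
}

#' Effective treatment multipliers under a mapping mode
#'
#' The published relative-risk table prints the triplet (stroke 0.38,
#' bleeding 0.74, mortality 2.40). Read literally, anticoagulation would
#' reduce bleeding and more than double mortality, which contradicts the
#' meta-analytic evidence the table cites (stroke RR ~0.38, mortality RR
#' ~0.74, major bleeding increased). The default `clinically_coherent` mode
#' therefore maps the printed values to \{stroke 0.38, bleed 2.40,
#' mortality 0.74\}; `literal_table` applies them exactly as printed.
#'
#' @param effect the `effect` component of an `af_params` object.
#' @return named list with `m_stroke`, `m_bleed`, `m_mortality`.
#' @export
effective_multipliers <- function(effect) {
  mode <- effect$mapping_mode
  if (identical(mode, "clinically_coherent")) {
    list(m_stroke = effect$rr_stroke,
         m_bleed = effect$rr_mortality,  # 2.40: bleeding risk raised
         m_mortality = effect$rr_bleed)  # 0.74: all-cause mortality reduced
  } else if (identical(mode, "literal_table")) {
    list(m_stroke = effect$rr_stroke,
         m_bleed = effect$rr_bleed,
         m_mortality = effect$rr_mortality)
  } else {
    stop("unknown mapping_mode: ", mode, call. = FALSE)
  }
}

#' Apply treatment relative risks to event probabilities
#'
#' Scales the untreated per-cycle probabilities by the effective treatment
#' multipliers: stroke probabilities (including the acutely fatal fraction)
#' by the stroke multiplier, bleeding probabilities by the bleed multiplier,
#' and background (age-related) mortality by the mortality multiplier.
#' Post-stroke death is left untouched: event-specific mortality is governed
#' by its own probability. Results are clamped to `[0, 1]` with a warning.
#'
#' @param events the `events` component of an `af_params` object.
#' @param effect the `effect` component.
#' @param lifetable_q per-cycle background death probability to adjust.
#' @return list with elements `events` (scaled probabilities) and `q`
#'   (adjusted background mortality).
#' @export
treated_probabilities <- function(events, effect, lifetable_q = 0) {
  m <- effective_multipliers(effect)
  out <- events
  out$p_stroke <- events$p_stroke * m$m_stroke
  out$p_stroke_acute_death <- events$p_stroke_acute_death * m$m_stroke
  out$p_major_bleed <- events$p_major_bleed * m$m_bleed
  out$p_bleed_acute_death <- events$p_bleed_acute_death * m$m_bleed
  q <- lifetable_q * m$m_mortality
  vals <- c(unlist(out), q)
  if (any(vals > 1) || any(vals < 0)) {
    warning("treated probabilities clamped to [0, 1]", call. = FALSE)
    out <- lapply(out, function(x) min(max(x, 0), 1))
    q <- min(max(q, 0), 1)
  }
  list(events = out, q = q)
}

#' Build a beta distribution specification from a mean and range
#'
#' Method-of-moments beta on the support `[0, scale]`, with the standard
#' deviation taken as `(upper - lower) / (2 * 1.96)` (the range read as a
#' 95% interval). Probabilities and utilities use `scale = 1`; costs use
#' `scale = 2 * mean` so that a symmetric +/-20% range fits inside a
#' bounded support. A zero-width range yields a degenerate `fixed` spec.
#'
#' @param mean central value (`> 0` unless `lower == upper == mean`).
#' @param lower,upper range bounds, `lower <= mean <= upper`. Default
#'   `mean` +/- 20%.
#' @param scale support upper bound; default 1.
#' @return an `af_dist` list: `family` (`"beta_scaled"` or `"fixed"`),
#'   `mean`, `lower`, `upper`, `scale` and, for betas, `alpha`, `beta`.
#' @examples
#' beta_spec_from_mean(0.5, 0.5 - 1.96 * 0.05, 0.5 + 1.96 * 0.05) # alpha=beta=49.5
#' @export
beta_spec_from_mean <- function(mean, lower = 0.8 * mean, upper = 1.2 * mean,
                                scale = 1) {
  if (!(lower <= mean && mean <= upper)) {
    stop("need lower <= mean <= upper", call. = FALSE)
  }
  sd <- (upper - lower) / (2 * 1.96)
  if (sd == 0) {
    return(structure(list(family = "fixed", mean = mean, lower = lower,
                          upper = upper, scale = scale),
                     class = "af_dist"))
  }
  if (mean <= 0 || mean >= scale) {
    stop("mean must lie strictly inside (0, scale) for a beta spec",
         call. = FALSE)
  }
  mu <- mean / scale
  sigma2 <- (sd / scale)^2
  if (sigma2 >= mu * (1 - mu)) {
    stop("variance too large for a beta distribution on [0, ", scale,
         "]; treat this parameter as fixed or widen the scale", call. = FALSE)
  }
  alpha <- mu * (mu * (1 - mu) / sigma2 - 1)
  beta <- alpha * (1 - mu) / mu
  structure(list(family = "beta_scaled", mean = mean, lower = lower,
                 upper = upper, scale = scale, alpha = alpha, beta = beta),
            class = "af_dist")
}

#' Fixed (degenerate) distribution specification
#' @param mean the fixed value.
#' @return an `af_dist` object of family `"fixed"`.
#' @export
fixed_spec <- function(mean) {
  structure(list(family = "fixed", mean = mean, lower = mean, upper = mean,
                 scale = 1), class = "af_dist")
}

#' Draw one value from a distribution specification
#' @param spec an `af_dist` object.
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
draw_spec <- function(spec, n = 1) {
  if (spec$family == "fixed") {
    rep(spec$mean, n)
  } else {
    spec$scale * stats::rbeta(n, spec$alpha, spec$beta)
  }
}

#' Default PSA distribution set
#'
#' Assigns every varied model parameter its sampling distribution for the
#' probabilistic sensitivity analysis: beta distributions with a +/-20%
#' range around the base value for event probabilities, utilities (the
#' bleed-state utility is derived as `u_af - d_bleed`, so `u_af` and
#' `d_bleed` are the sampled quantities), event costs (on a `[0, 2*mean]`
#' support), treatment-effect multipliers and persistence. Treatment costs
#' (drug, INR monitoring) and all screening-cascade inputs are fixed.
#'
#' @param params a parameter list (pre-validation is fine).
#' @return named list of `af_dist` specs keyed by dotted parameter path.
#' @export
default_psa_distributions <- function(params) {
  specs <- list()
  band <- function(x, scale = 1) {
    # boundary values (e.g. a utility of exactly 0 or 1) cannot carry a
    # beta distribution; hold them fixed
    if (x <= 0 || x >= scale) return(fixed_spec(x))
    beta_spec_from_mean(x, 0.8 * x, 1.2 * x, scale)
  }
  for (nm in names(params$events)) {
    specs[[paste0("events.", nm)]] <- band(params$events[[nm]])
  }
  for (nm in c("u_af", "u_acute_stroke", "u_post_stroke", "d_bleed")) {
    specs[[paste0("utilities.", nm)]] <- band(params$utilities[[nm]])
  }
  for (nm in c("c_acute_stroke", "c_post_stroke", "c_stroke_death",
               "c_major_bleed", "c_bleed_death")) {
    x <- params$costs[[nm]]
    specs[[paste0("costs.", nm)]] <- band(x, scale = 2 * x)
  }
  for (nm in c("c_noac", "c_warfarin", "c_inr")) {
    specs[[paste0("costs.", nm)]] <- fixed_spec(params$costs[[nm]])
  }
  for (nm in c("rr_stroke", "rr_bleed", "rr_mortality")) {
    x <- params$effect[[nm]]
    specs[[paste0("effect.", nm)]] <- band(x, scale = 2 * x)
  }
  for (nm in c("persist_first_cycle", "persist_later")) {
    specs[[paste0("persistence.", nm)]] <- band(params$persistence[[nm]])
  }
  specs
}

#' @export
print.af_params <- function(x, ...) {
  cat("AF screening model parameters\n")
  cat(sprintf("  cohort start age %g, %g-year cycles, %.0f%% annual discount\n",
              x$cycle$start_age, x$cycle$cycle_length,
              100 * x$cycle$discount_rate))
  cat(sprintf("  6-month probabilities: stroke %.4f, major bleed %.4f, post-stroke death %.4f\n",
              x$events$p_stroke, x$events$p_major_bleed,
              x$events$p_post_stroke_death))
  m <- effective_multipliers(x$effect)
  cat(sprintf("  anticoagulation effect (%s): stroke x%.2f, bleed x%.2f, mortality x%.2f\n",
              x$effect$mapping_mode, m$m_stroke, m$m_bleed, m$m_mortality))
  cat(sprintf("  treatment mix: %.0f%% NOAC ($%g/6mo) / %.0f%% warfarin ($%g + $%g INR)\n",
              100 * x$mix$frac_noac, x$costs$c_noac,
              100 * (1 - x$mix$frac_noac), x$costs$c_warfarin, x$costs$c_inr))
  cat(sprintf("  screening: %s people, %.0f%% attendance, %.1f%% AF prevalence, %.0f%% unknown\n",
              format(x$screening$population, big.mark = ","),
              100 * x$screening$attendance, 100 * x$screening$prevalence,
              100 * x$screening$unknown_af))
  cat(sprintf("  WTP threshold: $%g per QALY\n", x$wtp))
  invisible(x)
}
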