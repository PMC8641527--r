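# Shared fixtures: base parameters, a cheap flat life table for unit tests,
# and a lazily calibrated table reused across files.

base_params <- function(...) af_parameters(...)

# constant annual mortality, terminal at max_age
flat_life_table <- function(q = 0.04, start_age = 0, terminal_age = 110) {
  ages <- start_age:terminal_age
  qs <- rep(q, length(ages))
  qs[length(qs)] <- 1
  lt <- data.frame(age = as.integer(ages), q_annual = qs)
  class(lt) <- c("af_life_table", "data.frame")
  lt
}

# all-zero hazard with no terminal jump: the cohort never ages out (used to
# probe null dynamics; not a loadable table, which requires a terminal age)
zero_life_table <- function() {
  lt <- data.frame(age = 0:200, q_annual = 0)
  class(lt) <- c("af_life_table", "data.frame")
  lt
}

# calibrated table is used by many files; compute once per test run
calibrated_lt <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(calibrated_life_table(base_params()))
    }
    cache
  }
})

# parameters with every treatment effect neutral and all treatment-related
# costs zero: the two arms must then be indistinguishable
null_treatment_params <- function() {
  af_parameters(
    effect = list(rr_stroke = 1, rr_bleed = 1, rr_mortality = 1),
    costs = list(c_noac = 0, c_warfarin = 0, c_inr = 0)
  )
}

run_cea_quiet <- function(...) suppressWarnings(run_cea(...))
run_cascade_quiet <- function(p) suppressWarnings(run_cascade(p))
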