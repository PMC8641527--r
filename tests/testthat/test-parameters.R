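test_that("defaults reproduce the published base-case inputs exactly", {
  p <- base_params()
  frozen <- list(
    events = list(p_stroke = 0.0108, p_stroke_acute_death = 0.0023,
                  p_post_stroke_death = 0.1751, p_major_bleed = 0.0013,
                  p_bleed_acute_death = 0.0001),
    utilities = list(u_af = 0.8430, u_acute_stroke = 0.3280,
                     u_post_stroke = 0.5490, u_major_bleed = 0.8140,
                     d_bleed = 0.029),
    costs = list(c_acute_stroke = 938, c_post_stroke = 6, c_stroke_death = 1126,
                 c_major_bleed = 195, c_bleed_death = 778, c_noac = 448,
                 c_warfarin = 17, c_inr = 30),
    effect = list(rr_stroke = 0.38, rr_bleed = 0.74, rr_mortality = 2.40)
  )
  for (grp in names(frozen)) {
    for (nm in names(frozen[[grp]])) {
      expect_identical(p[[grp]][[nm]], frozen[[grp]][[nm]],
                       label = paste(grp, nm, sep = "."))
    }
  }
  expect_identical(p$cycle$cycle_length, 0.5)
  expect_identical(p$cycle$discount_rate, 0.04)
  expect_identical(p$cycle$start_age, 55)
  expect_identical(p$persistence$persist_first_cycle, 0.70)
  expect_identical(p$persistence$persist_later, 0.60)
  expect_identical(p$screening$population, 9053294)
  expect_identical(p$wtp, 2000)
  # cost-table internal relations
  expect_equal(p$costs$c_stroke_death, 1.2 * p$costs$c_acute_stroke, tolerance = 0.01)
  expect_equal(p$costs$c_bleed_death, 4 * p$costs$c_major_bleed, tolerance = 0.01)
  expect_equal(p$utilities$u_major_bleed, p$utilities$u_af - p$utilities$d_bleed)
})

test_that("parameter validation reports all violations and rejects unknown keys", {
  expect_error(af_parameters(events = list(p_stroke = 1.5)), "p_stroke")
  err <- tryCatch(
    af_parameters(events = list(p_stroke = 1.5), wtp = -1),
    error = function(e) conditionMessage(e)
  )
  expect_match(err, "p_stroke")
  expect_match(err, "wtp")
  expect_error(af_parameters(nonsense = 1), "unknown parameter key")
  expect_error(af_parameters(events = list(p_banana = 1)), "p_banana")
})

test_that("YAML round trip preserves the bundle; malformed files error", {
  p <- base_params()
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, tmp)
  p2 <- load_parameters(tmp)
  expect_equal(p2$events, p$events)
  expect_equal(p2$costs, p$costs)
  expect_equal(p2$screening, p$screening)
  expect_error(load_parameters("no/such/file.yaml"), "not found")

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("events:\n  p_stroke: 2.0", bad)
  expect_error(load_parameters(bad), "p_stroke")
})

test_that("to_cycle_probability matches the constant-hazard formula", {
  expect_identical(to_cycle_probability(0, 1, 0.5), 0)
  expect_identical(to_cycle_probability(1, 1, 0.5), 1)
  # annual 0.0215 halves to the published 6-month stroke probability
  expect_equal(to_cycle_probability(0.0215, 1, 0.5), 1 - (1 - 0.0215)^0.5)
  expect_equal(round(to_cycle_probability(0.0215, 1, 0.5), 4), 0.0108)
  expect_error(to_cycle_probability(1.2, 1, 0.5), "\\[0, 1\\]")
  expect_error(to_cycle_probability(0.5, 0, 0.5), "positive")
})

test_that("cycle-probability conversion round-trips to 1e-12", {
  set.seed(11)
  p <- runif(200)
  back <- to_cycle_probability(to_cycle_probability(p, 1, 0.5), 0.5, 1)
  expect_true(max(abs(back - p)) < 1e-12)
})

test_that("effective multipliers honour the mapping mode", {
  eff <- base_params()$effect
  m <- effective_multipliers(eff)
  expect_equal(m$m_stroke, 0.38)
  expect_equal(m$m_bleed, 2.40)
  expect_equal(m$m_mortality, 0.74)
  eff$mapping_mode <- "literal_table"
  m2 <- effective_multipliers(eff)
  expect_equal(m2$m_bleed, 0.74)
  expect_equal(m2$m_mortality, 2.40)
})

test_that("treated_probabilities scales, is monotone, identity at 1, clamps", {
  p <- base_params()
  tp <- treated_probabilities(p$events, p$effect, lifetable_q = 0.02)
  expect_equal(tp$events$p_stroke, 0.0108 * 0.38)
  expect_equal(tp$events$p_major_bleed, 0.0013 * 2.40)
  expect_equal(tp$q, 0.02 * 0.74)

  id <- list(rr_stroke = 1, rr_bleed = 1, rr_mortality = 1,
             mapping_mode = "clinically_coherent")
  tp_id <- treated_probabilities(p$events, id, lifetable_q = 0.02)
  expect_equal(tp_id$events, p$events)
  expect_equal(tp_id$q, 0.02)

  # monotone in each multiplier
  for (nm in c("rr_stroke", "rr_bleed", "rr_mortality")) {
    lo <- hi <- p$effect
    lo[[nm]] <- 0.5 * p$effect[[nm]]
    hi[[nm]] <- 2.0 * p$effect[[nm]]
    a <- unlist(treated_probabilities(p$events, lo, 0.02))
    b <- unlist(treated_probabilities(p$events, hi, 0.02))
    expect_true(all(b >= a))
  }

  big <- list(rr_stroke = 200, rr_bleed = 1, rr_mortality = 1,
              mapping_mode = "clinically_coherent")
  expect_warning(treated_probabilities(p$events, big, 0), "clamped")
})

test_that("beta specs match method-of-moments and their Monte Carlo moments", {
  # mean 0.5, sd 0.05 on the unit interval -> alpha = beta = 49.5
  spec <- beta_spec_from_mean(0.5, 0.5 - 1.96 * 0.05, 0.5 + 1.96 * 0.05)
  expect_equal(spec$alpha, 49.5)
  expect_equal(spec$beta, 49.5)

  expect_identical(beta_spec_from_mean(0.5, 0.5, 0.5)$family, "fixed")
  expect_error(beta_spec_from_mean(0.5, -3, 4), "variance too large")
  expect_error(beta_spec_from_mean(0.7, 0.5, 0.9, scale = 0.6), "inside")

  set.seed(91)
  for (spec in list(beta_spec_from_mean(0.0108),
                    beta_spec_from_mean(938, scale = 2 * 938))) {
    x <- draw_spec(spec, 1e5)
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - spec$mean), 3 * se)
    expect_true(all(x >= 0 & x <= spec$scale))
  }
})

test_that("default PSA distribution set fixes treatment costs and varies the rest", {
  p <- base_params()
  expect_identical(p$psa[["costs.c_noac"]]$family, "fixed")
  expect_identical(p$psa[["costs.c_warfarin"]]$family, "fixed")
  expect_identical(p$psa[["costs.c_inr"]]$family, "fixed")
  expect_identical(p$psa[["events.p_stroke"]]$family, "beta_scaled")
  expect_identical(p$psa[["utilities.u_af"]]$family, "beta_scaled")
  expect_equal(p$psa[["events.p_stroke"]]$mean, 0.0108)
  # no distribution for screening totals: cascade inputs are not in the set
  expect_false(any(grepl("^screening\\.", names(p$psa))))
})
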