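test_that("on-treatment fractions follow the persistence schedule", {
  pe <- base_params()$persistence
  expect_equal(on_treatment_fraction(1, "screening", pe), 0.70)
  expect_equal(on_treatment_fraction(2, "screening", pe), 0.60)
  expect_equal(on_treatment_fraction(5, "screening", pe), 0.60)
  expect_equal(on_treatment_fraction(3, "no_screening", pe), 0)
  # stroke survivors are treated in both arms, clocked from onset
  expect_equal(on_treatment_fraction(9, "no_screening", pe, "ACUTE_STROKE"), 0.70)
  expect_equal(on_treatment_fraction(9, "no_screening", pe, "POST_STROKE"), 0.60)
  expect_equal(on_treatment_fraction(9, "screening", pe, "ACUTE_BLEED"), 0)
})

test_that("transition rows are stochastic, absorbing states are identities", {
  p <- base_params()
  lt <- flat_life_table(0.05)
  for (arm in c("screening", "no_screening")) {
    for (cyc in c(1, 2, 30, 80)) {
      P <- build_transition_matrix(p, arm, lt, cyc)
      expect_equal(unname(rowSums(P)), rep(1, 8),
                   tolerance = 1e-12, label = paste(arm, cyc))
      expect_true(all(P >= 0))
      for (s in c("DEAD_STROKE_ACUTE", "DEAD_POST_STROKE", "DEAD_BLEED", "DEAD_AGE")) {
        expect_identical(unname(P[s, s]), 1)
      }
    }
  }
  # untreated AF row with q = 0: stay probability is the event complement
  P0 <- build_transition_matrix(p, "no_screening", zero_life_table(), 1)
  expect_equal(P0["AF", "AF"], 1 - 0.0108 - 0.0013)
  expect_equal(P0["AF", "ACUTE_STROKE"], 0.0108 - 0.0023)
  expect_equal(P0["AF", "DEAD_STROKE_ACUTE"], 0.0023)
  # tunnel: acute stroke fully vacates within one cycle
  expect_identical(unname(P0["ACUTE_STROKE", "ACUTE_STROKE"]), 0)
  expect_identical(unname(P0["ACUTE_BLEED", "ACUTE_BLEED"]), 0)
})

test_that("over-subscribed event probabilities raise a model-consistency error", {
  p <- af_parameters(events = list(p_stroke = 0.7, p_stroke_acute_death = 0.1,
                                   p_major_bleed = 0.5, p_bleed_acute_death = 0.1))
  expect_error(run_cohort(p, "no_screening", flat_life_table(0.01)),
               "over-subscribed")
})

test_that("cohort propagation conserves mass and matches the matrix route", {
  p <- base_params()
  lt <- calibrated_lt()
  for (arm in c("screening", "no_screening")) {
    tr <- run_cohort(p, arm, lt)
    expect_true(max(abs(rowSums(tr$occupancy) - 1)) < 1e-10)
    # absorbing occupancy never decreases
    for (j in 5:8) expect_true(all(diff(tr$occupancy[, j]) >= -1e-15))

    occ <- matrix(0, nrow(tr$occupancy), 8)
    occ[1, 1] <- 1
    for (k in seq_len(nrow(occ) - 1)) {
      occ[k + 1, ] <- occ[k, ] %*% build_transition_matrix(p, arm, lt, k)
    }
    expect_equal(unname(tr$occupancy), occ, tolerance = 1e-12)
  }
})

test_that("null dynamics freeze the cohort in AF", {
  p <- af_parameters(events = list(p_stroke = 0, p_stroke_acute_death = 0,
                                   p_major_bleed = 0, p_bleed_acute_death = 0))
  tr <- suppressWarnings(run_cohort(p, "screening", zero_life_table()))
  expect_true(all(tr$occupancy[, 1] == 1))
  expect_true(all(tr$occupancy[, -1] == 0))
})

test_that("outcome accounting: discounting, QALY bounds, cost components", {
  p <- base_params()
  lt <- calibrated_lt()
  tr <- run_cohort(p, "screening", lt)
  out <- trace_outcomes(tr, p)
  pc <- out$per_cycle
  expect_identical(pc$discount[1], 1)
  expect_equal(pc$discount[3], 1 / 1.04) # cycle 2 = one year out
  # QALYs <= LYs, discounted <= undiscounted
  expect_true(out$totals$discounted$qaly <= out$totals$discounted$ly)
  for (f in c("ly", "qaly", "cost")) {
    expect_true(out$totals$discounted[[f]] <= out$totals$undiscounted[[f]],
                label = f)
  }
  expect_equal(pc$cost, pc$cost_treatment + pc$cost_events + pc$cost_upkeep)

  # all utilities 1 makes QALYs equal LYs
  p1 <- af_parameters(utilities = list(u_af = 1, u_acute_stroke = 1,
                                       u_post_stroke = 1, u_major_bleed = 1,
                                       d_bleed = 0))
  out1 <- trace_outcomes(run_cohort(p1, "screening", lt), p1)
  expect_equal(out1$totals$discounted$qaly, out1$totals$discounted$ly)

  # warfarin mix swaps drug pricing: NOAC 448 vs warfarin 17 + INR 30
  out_w <- trace_outcomes(tr, p, mix = 0)
  expect_equal(out_w$totals$discounted$cost_treatment / 47,
               out$totals$discounted$cost_treatment / 448)
})

test_that("bleed events can be priced without the tunnel state", {
  lt <- calibrated_lt()
  p_nt <- af_parameters(options = list(bleed_tunnel = FALSE))
  tr <- run_cohort(p_nt, "screening", lt)
  expect_true(all(tr$occupancy[, "ACUTE_BLEED"] == 0))
  expect_true(sum(tr$entries[, "nonfatal_bleed"]) > 0)
  out <- trace_outcomes(tr, p_nt)
  # bleed costs still accrue through event entries
  expect_true(out$totals$discounted$cost_events >
                sum(tr$entries[, "nonfatal_stroke"]) * 0) # non-degenerate
  p_t <- base_params()
  out_t <- trace_outcomes(run_cohort(p_t, "screening", lt), p_t)
  # both conventions land close: one-cycle utility/cost hit either way
  expect_equal(out$totals$discounted$qaly, out_t$totals$discounted$qaly,
               tolerance = 0.02)
})

test_that("median survival interpolates the 50% crossing", {
  p <- base_params()
  # certain death in the first cycle
  tr1 <- suppressWarnings(run_cohort(p, "no_screening", flat_life_table(1, 0, 110)))
  expect_lt(median_survival(tr1), 0.5 + 1e-9)
  # monotone survival: unique crossing, finite value
  tr <- run_cohort(p, "no_screening", calibrated_lt())
  expect_true(all(diff(tr$living) <= 1e-15))
  m <- median_survival(tr)
  expect_true(is.finite(m) && m > 0)
  # never crossing
  tr0 <- suppressWarnings(run_cohort(
    af_parameters(events = list(p_stroke = 0, p_stroke_acute_death = 0,
                                p_major_bleed = 0, p_bleed_acute_death = 0)),
    "screening", zero_life_table()))
  expect_warning(expect_true(is.na(median_survival(tr0))), "undefined")
})

test_that("trace CSV export round-trips occupancy and outcomes", {
  p <- base_params()
  tr <- run_cohort(p, "screening", calibrated_lt())
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, tmp, params = p)
  df <- read.csv(tmp)
  expect_equal(nrow(df), nrow(tr$occupancy))
  expect_equal(df$AF, unname(tr$occupancy[, "AF"]))
  expect_true(all(c("qaly", "cost", "discount", "qaly_disc") %in% names(df)))
})
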