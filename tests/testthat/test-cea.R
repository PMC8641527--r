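test_that("arm totals scale per-patient outcomes and book screening costs once", {
  p <- base_params()
  lt <- calibrated_lt()
  cs <- run_cascade_quiet(p)
  out <- trace_outcomes(run_cohort(p, "screening", lt), p)

  arm <- arm_totals(out, cs, include_screening = TRUE)
  n <- cs$cohort_size
  expect_equal(arm$total$discounted$qaly, out$totals$discounted$qaly * n)
  expect_equal(arm$per_patient$discounted$qaly, out$totals$discounted$qaly)
  expect_equal(arm$total$discounted$cost,
               out$totals$discounted$cost * n + cs$cost_total)
  expect_equal(arm$total$discounted$cost_screening, cs$cost_total)
  # components sum to the total
  t <- arm$total$discounted
  expect_equal(t$cost, t$cost_treatment + t$cost_events + t$cost_upkeep +
                 t$cost_screening)
  # screening cost is undiscounted (t = 0) hence equal in both panels
  expect_equal(arm$total$undiscounted$cost_screening, cs$cost_total)

  no_scr <- arm_totals(out, cs, include_screening = FALSE)
  expect_equal(no_scr$total$discounted$cost, out$totals$discounted$cost * n)

  cs1 <- cs
  cs1$cohort_size <- 1
  arm1 <- arm_totals(out, cs1, include_screening = FALSE)
  expect_equal(arm1$total$discounted$qaly, out$totals$discounted$qaly)

  cs0 <- cs
  cs0$cohort_size <- 0
  expect_error(arm_totals(out, cs0), "empty cohort")
})

test_that("icer arithmetic, dominance quadrants and NMB behave as defined", {
  p <- base_params()
  lt <- calibrated_lt()
  cs <- run_cascade_quiet(p)
  out_s <- trace_outcomes(run_cohort(p, "screening", lt), p)
  out_n <- trace_outcomes(run_cohort(p, "no_screening", lt), p)
  a <- arm_totals(out_s, cs, TRUE)
  b <- arm_totals(out_n, cs, FALSE)

  ce <- icer(a, b, wtp = 2000)
  d <- ce$delta$discounted
  expect_equal(ce$icer, d$cost / d$qaly)
  expect_equal(ce$delta$per_patient$qaly, d$qaly / ce$n)
  expect_equal(ce$nmb, 2000 * d$qaly / ce$n - d$cost / ce$n)

  # dominance quadrants via synthetic arm results
  fake <- function(q, c) {
    r <- a
    for (w in c("discounted", "undiscounted")) {
      r$total[[w]]$qaly <- b$total[[w]]$qaly + q
      r$total[[w]]$cost <- b$total[[w]]$cost + c
    }
    r
  }
  expect_identical(icer(fake(10, -500), b)$dominance, "dominant")
  expect_identical(icer(fake(-10, 500), b)$dominance, "dominated")
  expect_identical(icer(fake(0, 500), b)$dominance, "undefined")
  expect_equal(icer(fake(10, 500), b)$icer, 50)

  mism <- b
  mism$n <- b$n + 1
  expect_error(icer(a, mism), "different cohort sizes")

  # published consistency example: 0.41 QALY and $564 at WTP $2,000
  expect_equal(nmb_value(0.41, 564, 2000), 256)
  expect_lt(nmb_value(0.41, 5205, 2000), 0)
  expect_equal(nmb_value(0.41, 2000 * 0.41, 2000), 0)
  expect_error(nmb_value(1, 1, 0), "positive")
})

test_that("null treatment effects make the two arms identical", {
  p <- null_treatment_params()
  lt <- calibrated_lt()
  tr_s <- run_cohort(p, "screening", lt)
  tr_n <- run_cohort(p, "no_screening", lt)
  expect_equal(tr_s$occupancy, tr_n$occupancy, tolerance = 1e-15)
  out_s <- trace_outcomes(tr_s, p)
  out_n <- trace_outcomes(tr_n, p)
  expect_equal(out_s$totals$discounted$qaly, out_n$totals$discounted$qaly)
  expect_equal(out_s$totals$discounted$cost, out_n$totals$discounted$cost)

  p0 <- modify_parameters(p, list(include_screening_cost_in_icer = FALSE))
  ce <- run_cea_quiet(p0, lt)
  expect_identical(ce$ce$dominance, "undefined")
  expect_equal(ce$ce$delta$discounted$cost, 0, tolerance = 1e-6)
})

test_that("full CEA satisfies its own cross-arithmetic identities", {
  p <- base_params()
  lt <- calibrated_lt()
  ce <- run_cea_quiet(p, lt)
  d <- ce$ce$delta$discounted
  expect_equal(ce$ce$icer, d$cost / d$qaly)
  expect_equal(ce$ce$delta$per_patient$qaly * ce$cascade$cohort_size, d$qaly)
  # screening arm longer-lived and costlier under active treatment effects
  expect_gt(ce$median_survival["screening"], ce$median_survival["no_screening"])
  expect_gt(d$qaly, 0)
  expect_gt(d$cost, 0)
})

test_that("ICER ordering across treatment mixes follows drug cost", {
  p <- base_params()
  lt <- calibrated_lt()
  i_war <- run_cea_quiet(p, lt, mix = 0)$ce$icer
  i_mix <- run_cea_quiet(p, lt, mix = 0.5)$ce$icer
  i_noac <- run_cea_quiet(p, lt, mix = 1)$ce$icer
  expect_true(i_war <= i_mix && i_mix <= i_noac)
})

test_that("results report mirrors the arm totals in both discount panels", {
  p <- base_params()
  lt <- calibrated_lt()
  rep <- suppressWarnings(table5_report(p, lt, mixes = c(noac = 1, warfarin = 0)))
  expect_s3_class(rep, "data.frame")
  expect_equal(nrow(rep), 2 * 2 * 3)

  noac_d <- rep[rep$mix == "noac" & rep$discounting == "discounted", ]
  delta <- noac_d[noac_d$row == "delta", ]
  on_t <- noac_d[noac_d$row == "on_treatment", ]
  no_t <- noac_d[noac_d$row == "no_treatment", ]
  expect_equal(delta$qalys, on_t$qalys - no_t$qalys)
  expect_equal(delta$costs, on_t$costs - no_t$costs)
  expect_equal(delta$icer, delta$costs / delta$qalys)

  # undiscounted ICER below discounted in the base case (costs accrue late)
  noac_u <- rep[rep$mix == "noac" & rep$discounting == "undiscounted", ]
  expect_lt(noac_u$icer[noac_u$row == "delta"], delta$icer)

  tmp_csv <- withr::local_tempfile(fileext = ".csv")
  tmp_json <- withr::local_tempfile(fileext = ".json")
  write_report(rep, tmp_csv)
  write_report(rep, tmp_json)
  expect_equal(nrow(read.csv(tmp_csv)), nrow(rep))
  expect_equal(length(jsonlite::read_json(tmp_json)), nrow(rep))
})
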