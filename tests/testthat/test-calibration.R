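test_that("precavity backward-extrapolation follows the age gradient", {
  # mid-band estimate: (old - mid) increment scaled by residence ratio 18/48
  out <- age_extrapolate_precavity(0.02, 0.10, 0.20)
  expect_equal(out[["toddler"]], (0.20 - 0.10) * 18 / 48)  # 0.0375
  expect_equal(out[["infant"]], (0.10 - 0.02) * 6 / 18)
  expect_equal(out[["preschool"]], 0.10)

  # constant prevalence: no growth, no precavity pipeline
  expect_equal(unname(age_extrapolate_precavity(0.1, 0.1, 0.1)), rep(0, 3))

  # disease confined to the oldest band: no infant pipeline
  expect_equal(age_extrapolate_precavity(0, 0, 0.3)[["infant"]], 0)

  # decreasing prevalence warns (twice: ordering, then clamping) and clamps
  expect_warning(
    expect_warning(out <- age_extrapolate_precavity(0.2, 0.1, 0.3),
                   "nondecreasing"),
    "clamped")
  expect_true(all(out >= 0))

  # vectorized over risk bands
  m <- age_extrapolate_precavity(c(0.01, 0.02), c(0.05, 0.10), c(0.10, 0.20))
  expect_equal(dim(m), c(3L, 2L))
})

test_that("calibrated baseline is near-stationary and matches its targets", {
  cal <- cached_cal()
  expect_true(cal$converged)
  expect_lt(stationarity_residual(cal$rates, cal$state), 1e-3)
  fin <- endpoint(ecc_run(cal$state, cal$rates, NULL, 120))
  m <- ecc_metrics(fin, cal$rates)
  tg <- ecc_params()$targets
  expect_equal(m$fraction_with_cavities, tg$overall_cavity_fraction,
               tolerance = 0.02)
  expect_equal(m$fraction_untreated_of_cavities, tg$untreated_of_cavities,
               tolerance = 0.02)
  expect_equal(m$total_dft, tg$total_dft, tolerance = 0.02)
  # per-risk prevalence preserves the survey risk gradient
  per_risk <- vapply(1:3, function(r)
    sum(fin$counts[, r, c("cavity_untreated", "cavity_symptomatic",
                          "cavity_treated", "precavity_recurrent")]) /
      sum(fin$counts[, r, ]), 0)
  expect_true(per_risk[3] > per_risk[2] && per_risk[2] > per_risk[1])
})

test_that("stationarity residual behaves like a fixed-point distance", {
  # closed demography with no flows: exact fixed point
  st <- make_initial_state(900, rep(1, 3) / 3, rep(1, 3) / 3,
                           one_stage_fractions("colonized"))
  expect_equal(stationarity_residual(still_rates(), st), 0)
  # empty population: residual defined as zero
  z <- make_initial_state(0, rep(1, 3) / 3, rep(1, 3) / 3,
                          one_stage_fractions())
  expect_equal(stationarity_residual(still_rates(), z), 0)
  # perturbing the rates moves the system off its fixed point
  cal <- cached_cal()
  doubled <- cal$rates
  for (f in ECC_FLOWS)
    doubled$flows[[f]] <- pmin(2 * doubled$flows[[f]], 0.9)
  expect_gt(stationarity_residual(doubled, cal$state),
            stationarity_residual(cal$rates, cal$state))
})

test_that("calibration is deterministic and no multistart beats the solution", {
  cal <- cached_cal()
  cal2 <- suppressWarnings(ecc_calibrate(ecc_params(), seed = 17))
  expect_identical(cal2$rates, cal$rates)
  expect_identical(cal2$residuals, cal$residuals)
  expect_true(all(cal$loss <= cal$start_losses + 1e-12))
})

test_that("calibrated progression rates respect the risk ordering", {
  fl <- cached_cal()$rates$flows
  for (f in c("colonization", "caries_onset", "cavitation")) {
    for (a in 2:3) {  # disease is concentrated beyond the infant band
      expect_gte(fl[[f]][a, "high"], fl[[f]][a, "moderate"] - 1e-9)
      expect_gte(fl[[f]][a, "moderate"], fl[[f]][a, "low"] - 1e-9)
    }
  }
})

test_that("calibration recovers the metrics of a known-rate equilibrium", {
  # generate targets by running a perturbed rate set to its equilibrium,
  # then calibrate against those targets and compare the reproduced metrics
  cal <- cached_cal()
  truth <- cal$rates
  truth$flows$caries_onset <- 1.3 * truth$flows$caries_onset
  truth$flows$cavitation <- 0.8 * truth$flows$cavitation
  eq <- endpoint(ecc_run(cal$state, truth, NULL, 600))
  tot <- state_total(eq)
  m_eq <- ecc_metrics(eq, truth)
  per_risk <- vapply(1:3, function(r)
    sum(eq$counts[, r, c("cavity_untreated", "cavity_symptomatic",
                         "cavity_treated", "precavity_recurrent")]) /
      sum(eq$counts[, r, ]), 0)
  cost_eq <- endpoint(ecc_run(eq, truth, NULL, 120))$cum_restorative_cost -
    eq$cum_restorative_cost
  p2 <- ecc_params(
    total_population = tot,
    age_shares = apply(eq$counts, 1, sum) / tot,
    risk_shares = apply(eq$counts, 2, sum) / tot,
    risk_prevalence = stats::setNames(per_risk, c("low", "moderate", "high")),
    targets = list(
      overall_cavity_fraction = m_eq$fraction_with_cavities,
      untreated_of_cavities = m_eq$fraction_untreated_of_cavities,
      symptomatic_of_cavities = m_eq$symptomatic_fraction,
      total_dft = sum(truth$mean_dft * apply(eq$counts, c(1, 3), sum)),
      ten_year_restorative_cost = cost_eq))
  sf <- eq$counts / rep(apply(eq$counts, c(1, 2), sum), times = 7)
  cal2 <- ecc_calibrate(p2, seed = 3, refine = FALSE, stage_fractions = sf)
  fin <- endpoint(ecc_run(cal2$state, cal2$rates, NULL, 120))
  m2 <- ecc_metrics(fin, cal2$rates)
  expect_equal(m2$fraction_with_cavities, m_eq$fraction_with_cavities,
               tolerance = 0.01)
  expect_equal(m2$fraction_untreated_of_cavities,
               m_eq$fraction_untreated_of_cavities, tolerance = 0.01)
  expect_equal(fin$cum_restorative_cost, cost_eq, tolerance = 0.01)
})

test_that("zeroed disease targets calibrate to zeroed progression rates", {
  p0 <- ecc_params(targets = list(overall_cavity_fraction = 0,
                                  total_dft = 0,
                                  ten_year_restorative_cost = 0,
                                  visit_rate_band = c(0, 0.05)),
                   profile = list(smutans_by_age = c(infant = 0, toddler = 0,
                                                     preschool = 0)))
  cal0 <- ecc_calibrate(p0, seed = 1, refine = FALSE)
  for (f in c("caries_onset", "cavitation", "recavitation", "symptomatic",
              "recurrence", "treatment_cavity"))
    expect_true(all(cal0$rates$flows[[f]] < 0.01))
})
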