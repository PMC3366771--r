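test_that("a step with all rates zero is the identity", {
  st <- make_initial_state(900, rep(1, 3) / 3, rep(1, 3) / 3,
                           one_stage_fractions("colonized"))
  out <- ecc_step(st, still_rates())
  expect_equal(out$counts, st$counts)
  expect_equal(out$time, 1)
})

test_that("a single flow moves the Euler balance exactly", {
  # 100 colonized children, onset 0.1/mo: one step leaves 90 colonized,
  # 10 precavity
  st <- make_initial_state(900, rep(1, 3) / 3, rep(1, 3) / 3,
                           one_stage_fractions("colonized"))
  out <- ecc_step(st, still_rates(list(caries_onset = 0.1)))
  expect_equal(as.vector(out$counts[, , "colonized"]), rep(90, 9))
  expect_equal(as.vector(out$counts[, , "precavity"]), rep(10, 9))
})

test_that("unstable or malformed rates are rejected", {
  st <- make_initial_state(900, rep(1, 3) / 3, rep(1, 3) / 3,
                           one_stage_fractions("colonized"))
  expect_error(ecc_step(st, still_rates(list(caries_onset = 1.5))),
               "smaller dt")
  expect_error(ecc_rates(list(caries_onset = NaN)), "NaN")
  expect_error(ecc_rates(list(caries_onset = -0.1)), "negative")
  expect_error(ecc_rates(list(not_a_flow = 0.1)), "valid flows")
})

test_that("trajectories conserve people and stay nonnegative", {
  cal <- cached_cal()
  traj <- ecc_run(cal$state, cal$rates, NULL, 120)
  totals <- vapply(traj$states, state_total, 0)
  # replacement births close the demography: total constant to 1e-9 relative
  expect_true(all(abs(totals - totals[1]) / totals[1] < 1e-9))
  expect_true(all(vapply(traj$states, function(s) all(s$counts >= 0), TRUE)))
  expect_length(traj$states, 121)
  # horizon 0 returns only the initial state
  expect_length(ecc_run(cal$state, cal$rates, NULL, 0)$states, 1)
  # accounting registers never decrease
  costs <- vapply(traj$states, `[[`, 0, "cum_restorative_cost")
  expect_true(all(diff(costs) >= 0))
})

test_that("Euler trajectories agree with the matrix-exponential closed form", {
  # with fixed rates the model is linear; the continuous-time solution
  # expm(A t) x0 is an independent oracle for the discrete stepper
  skip_if_not_installed("Matrix")
  cal <- cached_cal()
  M <- step_matrix(cal$rates, 1)
  A <- M - diag(nrow(M))
  x0 <- as.vector(cal$state$counts)
  for (h in c(12, 120)) {
    oracle <- as.vector(Matrix::expm(A * h) %*% x0)
    sim <- as.vector(endpoint(ecc_run(cal$state, cal$rates, NULL, h))$counts)
    big <- oracle >= 10   # per-stock relative agreement where stocks have mass
    expect_lt(max(abs(sim[big] - oracle[big]) / oracle[big]), 0.02)
    expect_lt(max(abs(sim[!big] - oracle[!big])), 0.5)  # sub-child stocks
  }
})

test_that("the calibrated baseline holds its reported metrics for 10 years", {
  cal <- cached_cal()
  mets <- trajectory_metrics(ecc_run(cal$state, cal$rates, NULL, 120))
  drift <- abs(mets$fraction_with_cavities - mets$fraction_with_cavities[1])
  expect_lt(max(drift), 0.005)  # within half a percentage point throughout
  drift_u <- abs(mets$fraction_untreated_of_cavities -
                   mets$fraction_untreated_of_cavities[1])
  expect_lt(max(drift_u), 0.005)
})

test_that("raising a treatment rate weakly lowers untreated-cavity stocks", {
  cal <- cached_cal()
  faster <- cal$rates
  faster$flows$treatment_cavity <- 2 * faster$flows$treatment_cavity
  a <- ecc_run(cal$state, cal$rates, NULL, 60)
  b <- ecc_run(cal$state, faster, NULL, 60)
  for (k in seq_along(a$states))
    expect_true(all(b$states[[k]]$counts[, , "cavity_untreated"] <=
                      a$states[[k]]$counts[, , "cavity_untreated"] + 1e-9))
})

test_that("raising a progression rate never lowers downstream prevalence", {
  cal <- cached_cal()
  faster <- cal$rates
  faster$flows$cavitation <- pmin(1.5 * faster$flows$cavitation, 0.9)
  a <- ecc_run(cal$state, cal$rates, NULL, 60)
  b <- ecc_run(cal$state, faster, NULL, 60)
  for (k in seq_along(a$states)) {
    pa <- sum(a$states[[k]]$counts[, , c("cavity_untreated",
                                         "cavity_symptomatic",
                                         "cavity_treated",
                                         "precavity_recurrent")])
    pb <- sum(b$states[[k]]$counts[, , c("cavity_untreated",
                                         "cavity_symptomatic",
                                         "cavity_treated",
                                         "precavity_recurrent")])
    expect_gte(pb, pa - 1e-9)
  }
})
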