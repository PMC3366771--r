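## Explicit-Euler advancement of the stock-flow system.

#' Advance the population state by one time step
#'
#' First-order (explicit Euler) balance of the disease-stage flows, the aging
#' chain (first-order outflow at 1/residence per band; children aging out of
#' the preschool band leave the model) and births (newborns enter the infant
#' band uncolonized, allocated over risk bands).
#'
#' @param state an `ecc_state`.
#' @param rates an `ecc_rates`.
#' @param dt step length in months; every rate x dt product must be <= 1.
#' @return The advanced `ecc_state`; attribute `"flows"` carries the realized
#'   step flows (restorative treatment visits, secondary-prevention treatment
#'   episodes, births and band-crossing aging flows) used by the cost
#'   accounting.
#' @examples
#' r <- ecc_rates(list(caries_onset = 0.1))
#' sf <- array(0, dim = c(3, 3, 7)); sf[, , 2] <- 1
#' s <- make_initial_state(900, c(1, 1, 1) / 3, c(1, 1, 1) / 3, sf)
#' s1 <- ecc_step(s, ecc_rates(list(caries_onset = 0.1),
#'                             residence_months = c(Inf, Inf, Inf)))
#' @export
ecc_step <- function(state, rates, dt = 1) {
  stopifnot(inherits(state, "ecc_state"), inherits(rates, "ecc_rates"))
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  ct <- state$counts
  maxrate <- max(vapply(rates$flows, max, 0), rates$aging[is.finite(rates$aging)])
  if (maxrate * dt > 1)
    stop("rate x dt exceeds 1 (max rate ", format(maxrate),
         "); use a smaller dt for stability", call. = FALSE)

  d <- array(0, dim = dim(ct), dimnames = dimnames(ct))
  for (f in ECC_FLOWS) {
    flux <- rates$flows[[f]] * ct[, , FLOW_FROM[[f]]] * dt
    d[, , FLOW_FROM[[f]]] <- d[, , FLOW_FROM[[f]]] - flux
    d[, , FLOW_TO[[f]]] <- d[, , FLOW_TO[[f]]] + flux
  }
  tv_flux <- rates$flows$treatment_cavity * ct[, , "cavity_untreated"] * dt
  ts_flux <- rates$flows$treatment_symptomatic * ct[, , "cavity_symptomatic"] * dt
  ct_flux <- rates$flows$caries_treatment * ct[, , "precavity"] * dt

  aging <- ifelse(is.finite(rates$aging), rates$aging, 0)
  out1 <- ct["infant", , ] * aging[1] * dt    # risk x stage
  out2 <- ct["toddler", , ] * aging[2] * dt
  out3 <- ct["preschool", , ] * aging[3] * dt
  d["infant", , ] <- d["infant", , ] - out1
  d["toddler", , ] <- d["toddler", , ] + out1 - out2
  d["preschool", , ] <- d["preschool", , ] + out2 - out3

  births <- if (is.null(rates$birth_inflow)) sum(out3) else
    rates$birth_inflow * dt
  d["infant", , "uncolonized"] <- d["infant", , "uncolonized"] +
    births * rates$birth_risk_shares

  newct <- ct + d
  if (any(newct < -1e-6))
    stop("stock driven below zero at t = ", state$time,
         " (explicit-Euler instability); use a smaller dt", call. = FALSE)
  newct[newct < 0] <- 0

  out <- new_state(newct, time = state$time + dt,
                   cum_restorative_visits =
                     state$cum_restorative_visits + sum(tv_flux) + sum(ts_flux),
                   cum_restorative_cost = state$cum_restorative_cost,
                   cum_program_cost = state$cum_program_cost)
  attr(out, "flows") <- list(
    treatment_visits = sum(tv_flux) + sum(ts_flux),
    caries_treatment_episodes = sum(ct_flux),
    births_by_risk = births * rates$birth_risk_shares,
    aging_infant_toddler = rowSums(out1),   # by risk
    aging_toddler_preschool = rowSums(out2)
  )
  out
}

#' Run the model over a horizon
#'
#' Repeatedly applies [ecc_step()], with an intervention scenario (if any)
#' modifying the rates from time 0 and its program-cost model accumulating
#' into the program-cost register. Restorative costs accumulate as treatment
#' visits times the blended office/general-anesthesia episode cost.
#'
#' @param state initial `ecc_state`.
#' @param rates calibrated `ecc_rates`.
#' @param scenario an `ecc_scenario`, or `NULL` for the no-intervention
#'   baseline.
#' @param horizon months to simulate (multiple of `dt`).
#' @param dt step length in months.
#' @param constants a [cost_constants()] set.
#' @return An `ecc_trajectory`: list of states of length `horizon/dt + 1`.
#' @export
ecc_run <- function(state, rates, scenario = NULL, horizon = 120, dt = 1,
                    constants = cost_constants()) {
  if (horizon < 0 || abs(horizon / dt - round(horizon / dt)) > 1e-9)
    stop("horizon must be a nonnegative multiple of dt", call. = FALSE)
  sim_rates <- if (is.null(scenario)) rates else apply_scenario(rates, scenario)
  n <- as.integer(round(horizon / dt))
  states <- vector("list", n + 1)
  ## one-time program costs charged to the stock present at program start
  if (!is.null(scenario))
    state$cum_program_cost <- state$cum_program_cost +
      program_cost_initial(scenario, state, constants)
  states[[1]] <- state
  for (k in seq_len(n)) {
    state <- tryCatch(ecc_step(state, sim_rates, dt), error = function(e)
      stop("step failed at time index ", k, ": ", conditionMessage(e),
           call. = FALSE))
    fl <- attr(state, "flows")
    state$cum_restorative_cost <- state$cum_restorative_cost +
      restorative_cost_increment(fl$treatment_visits, constants)
    if (!is.null(scenario))
      state$cum_program_cost <- state$cum_program_cost +
        program_cost_increment(scenario, state, constants, dt, flows = fl)
    states[[k + 1]] <- state
  }
  structure(list(states = states, dt = dt, horizon = horizon,
                 scenario_id = if (is.null(scenario)) "baseline" else
                   scenario$id,
                 rates = rates),
            class = "ecc_trajectory")
}

#' @export
print.ecc_trajectory <- function(x, ...) {
  cat("<ecc_trajectory>", x$scenario_id, "-", length(x$states), "states,",
      x$horizon, "months\n")
  print(x$states[[length(x$states)]])
  invisible(x)
}

#' Final state of a trajectory
#' @param traj an `ecc_trajectory`.
#' @export
endpoint <- function(traj) traj$states[[length(traj$states)]]

#' Metric time series of a trajectory
#'
#' @param traj an `ecc_trajectory`.
#' @return A data frame with one row per time step: the headline metrics of
#'   [ecc_metrics()] plus cumulative registers.
#' @export
trajectory_metrics <- function(traj) {
  rows <- lapply(traj$states, function(s) {
    m <- ecc_metrics(s, traj$rates)
    data.frame(time_months = s$time,
               fraction_with_cavities = m$fraction_with_cavities,
               fraction_untreated_of_cavities = m$fraction_untreated_of_cavities,
               symptomatic_fraction = m$symptomatic_fraction,
               total_dft = m$total_dft,
               total_population = state_total(s),
               cum_restorative_visits = s$cum_restorative_visits,
               cum_restorative_cost = s$cum_restorative_cost,
               cum_program_cost = s$cum_program_cost)
  })
  do.call(rbind, rows)
}

#' Tidy per-stratum trajectory export
#'
#' One row per (time, age band, risk band, stage).
#' @param x an `ecc_trajectory`.
#' @param ... unused.
#' @export
as.data.frame.ecc_trajectory <- function(x, ...) {
  do.call(rbind, lapply(x$states, as.data.frame))
}
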