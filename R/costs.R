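## Cost accounting: restorative-care costs, per-program costs, savings.

#' Cost constants
#'
#' Unit costs (2009 dollars) for restorative care and intervention programs.
#' The blended restorative episode mixes office care with the share of
#' children requiring treatment under general anesthesia.
#'
#' @param office_restorative_cost dollars per office restorative visit.
#' @param ga_episode_cost dollars per general-anesthesia care episode.
#' @param ga_fraction fraction of treated children requiring anesthesia care.
#' @param varnish_application_cost dollars per fluoride-varnish application.
#' @param maternal_xylitol_cost dollars per treated mother.
#' @param child_xylitol_cost dollars per child entering a xylitol program.
#' @param mi_cost dollars per family receiving motivational interviewing.
#' @param caries_management_cost dollars per secondary-prevention treatment
#'   episode (white-spot management).
#' @param fluoridation_cost_per_person_year dollars per covered person per
#'   year of community water fluoridation.
#' @param state_total_population_all_ages total population (all ages) of the
#'   jurisdiction, used only by population-wide cost models such as water
#'   fluoridation; an external input, not a property of the child cohort.
#' @return A `cost_constants` list.
#' @export
cost_constants <- function(office_restorative_cost = 276,
                           ga_episode_cost = 7204,
                           ga_fraction = 0.12,
                           varnish_application_cost = 16,
                           maternal_xylitol_cost = 100,
                           child_xylitol_cost = 100,
                           mi_cost = 100,
                           caries_management_cost = 242,
                           fluoridation_cost_per_person_year = 0.50,
                           state_total_population_all_ages = 5024748) {
  x <- list(office_restorative_cost = office_restorative_cost,
            ga_episode_cost = ga_episode_cost,
            ga_fraction = ga_fraction,
            varnish_application_cost = varnish_application_cost,
            maternal_xylitol_cost = maternal_xylitol_cost,
            child_xylitol_cost = child_xylitol_cost,
            mi_cost = mi_cost,
            caries_management_cost = caries_management_cost,
            fluoridation_cost_per_person_year = fluoridation_cost_per_person_year,
            state_total_population_all_ages = state_total_population_all_ages)
  num <- unlist(x[names(x) != "state_total_population_all_ages"])
  if (any(num < 0)) stop("cost constants must be nonnegative", call. = FALSE)
  if (ga_fraction > 1) stop("ga_fraction must lie in [0, 1]", call. = FALSE)
  structure(x, class = "cost_constants")
}

#' Inflation adjustment
#'
#' Compound annual adjustment, rounded to whole dollars (half up).
#' @param amount dollars in `from_year` terms.
#' @param from_year,to_year calendar years, `to_year >= from_year`.
#' @param rate annual inflation rate.
#' @examples
#' inflation_adjust(216, 2004, 2009, 0.05)  # 276
#' @export
inflation_adjust <- function(amount, from_year, to_year, rate = 0.05) {
  stopifnot(rate >= 0, to_year >= from_year)
  floor(amount * (1 + rate)^(to_year - from_year) + 0.5)
}

#' Restorative-care cost of a block of treatment visits
#'
#' @param visits number of restorative treatment episodes this step.
#' @param constants a [cost_constants()] set.
#' @return Dollars: `visits` times the blended episode cost
#'   `(1 - ga_fraction) * office + ga_fraction * anesthesia`.
#' @export
restorative_cost_increment <- function(visits, constants = cost_constants()) {
  stopifnot(all(visits >= 0))
  visits * ((1 - constants$ga_fraction) * constants$office_restorative_cost +
              constants$ga_fraction * constants$ga_episode_cost)
}

## Eligible children of a cost component: targeted (age x risk) stocks,
## regardless of disease stage (programs are population-targeted).
eligible_count <- function(state, ages, risks) {
  sum(state$counts[ages, risks, , drop = FALSE])
}

## One-time per-child program costs charged at program start to the stock
## already inside the eligible ages.
program_cost_initial <- function(scenario, state, constants) {
  tot <- 0
  for (comp in scenario$cost_components) {
    if (comp$model == "per_child_once")
      tot <- tot + eligible_count(state, comp$ages, comp$risks) *
        unit_cost_of(comp, constants)
  }
  tot
}

unit_cost_of <- function(comp, constants) {
  if (!is.null(comp[["unit_cost"]])) return(comp[["unit_cost"]])
  constants[[comp[["unit_cost_field"]]]]
}

#' Program cost accrued during one step
#'
#' Evaluates each cost component of a scenario:
#' \describe{
#'   \item{per_application}{eligible children x applications per year x unit
#'     cost x dt/12 (e.g. fluoride varnish).}
#'   \item{per_child_once}{unit cost for each child crossing into the
#'     eligible ages during the step (newborns for an all-ages program,
#'     band-crossing aging flows for age-gated ones); the initially eligible
#'     stock is charged once at program start.}
#'   \item{per_mother_once}{unit cost per mother of each child born into a
#'     targeted risk band during the step.}
#'   \item{per_treatment_episode}{unit cost per secondary-prevention
#'     treatment episode delivered during the step.}
#'   \item{population_wide}{jurisdiction population x covered fraction x
#'     unit cost per person-year x dt/12 (community water fluoridation).}
#'   \item{none}{0 (e.g. recurrence prevention folded into routine care).}
#' }
#'
#' @param scenario an `ecc_scenario`.
#' @param state the `ecc_state` after the step.
#' @param constants a [cost_constants()] set.
#' @param dt step length, months.
#' @param flows the step-flow list produced by [ecc_step()] (band-crossing
#'   aging flows, births, treatment episodes).
#' @return Dollars accrued this step.
#' @export
program_cost_increment <- function(scenario, state, constants, dt,
                                   flows = attr(state, "flows")) {
  tot <- 0
  for (comp in scenario$cost_components) {
    if (comp$model == "none") next
    uc <- unit_cost_of(comp, constants)
    tot <- tot + switch(
      comp$model,
      none = 0,
      per_application =
        eligible_count(state, comp$ages, comp$risks) *
          comp$applications_per_year * uc * dt / 12,
      per_child_once = {
        entering <- if ("infant" %in% comp$ages)
          sum(flows$births_by_risk[comp$risks])
        else if ("toddler" %in% comp$ages)
          sum(flows$aging_infant_toddler[comp$risks])
        else sum(flows$aging_toddler_preschool[comp$risks])
        entering * uc
      },
      per_mother_once = sum(flows$births_by_risk[comp$risks]) * uc,
      per_treatment_episode = flows$caries_treatment_episodes * uc,
      population_wide = {
        if (is.null(constants$state_total_population_all_ages))
          stop("population_wide cost model requires ",
               "state_total_population_all_ages", call. = FALSE)
        constants$state_total_population_all_ages * comp$coverage_fraction *
          uc * dt / 12
      },
      stop("unknown program cost model: ", comp$model, call. = FALSE)
    )
  }
  tot
}
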