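## Declarative intervention scenarios: rate-modifier specifications plus
## program-cost components, composable by multiplication of residual risks.

#' Define a rate-modifier effect
#'
#' @param flow a flow name from [ECC_FLOWS], or one of the convenience
#'   families `"decay"` (caries_onset + cavitation + recavitation: the
#'   demineralization flows a fluoride-type agent slows) and `"cavitation_path"`
#'   (cavitation + recavitation).
#' @param multiplier factor in \[0, 1\] applied to the targeted flow, usually
#'   `1 - efficacy x coverage`. Mutually exclusive with `set_from`.
#' @param set_from name of another flow whose (baseline) rate the targeted
#'   flow is set to, times `scale` — used by secondary-prevention scenarios
#'   that switch on white-spot treatment at the cavity-treatment rate.
#' @param scale scale factor for `set_from`.
#' @param ages,risks targeted age and risk bands (labels).
#' @return An effect specification list.
#' @export
ecc_effect <- function(flow, multiplier = NULL, set_from = NULL, scale = 1,
                       ages = AGE_LABELS, risks = RISK_LABELS) {
  flows <- switch(flow,
                  decay = c("caries_onset", "cavitation", "recavitation"),
                  cavitation_path = c("cavitation", "recavitation"),
                  flow)
  unknown <- setdiff(flows, ECC_FLOWS)
  if (length(unknown))
    stop("unknown flow name(s): ", paste(unknown, collapse = ", "),
         "; valid flows are: ", paste(ECC_FLOWS, collapse = ", "),
         call. = FALSE)
  if (is.null(multiplier) == is.null(set_from))
    stop("exactly one of multiplier or set_from must be given", call. = FALSE)
  if (!is.null(multiplier) && (multiplier < 0 || multiplier > 1))
    stop("multiplier must lie in [0, 1]", call. = FALSE)
  ages <- match.arg(ages, AGE_LABELS, several.ok = TRUE)
  risks <- match.arg(risks, RISK_LABELS, several.ok = TRUE)
  if (!length(ages) || !length(risks))
    stop("effect targets must be nonempty", call. = FALSE)
  list(flows = flows, multiplier = multiplier, set_from = set_from,
       scale = scale, ages = ages, risks = risks)
}

#' Define an intervention scenario
#'
#' @param id short label (Table-style, e.g. `"1.2"`).
#' @param description free text.
#' @param effects list of [ecc_effect()] specifications.
#' @param cost_components list of program-cost components, each a list with
#'   `model` (see [program_cost_increment()]), `unit_cost` or
#'   `unit_cost_field` (a [cost_constants()] field name), and model-specific
#'   fields (`ages`, `risks`, `applications_per_year`, `coverage_fraction`).
#' @return An `ecc_scenario`.
#' @export
ecc_scenario <- function(id, description = "", effects = list(),
                         cost_components = list()) {
  for (comp in cost_components) {
    if (is.null(comp$model)) stop("cost component lacks a model", call. = FALSE)
    if (!is.null(comp[["unit_cost"]]) && comp[["unit_cost"]] < 0)
      stop("unit_cost must be nonnegative", call. = FALSE)
  }
  structure(list(id = id, description = description, effects = effects,
                 cost_components = cost_components),
            class = "ecc_scenario")
}

#' @export
print.ecc_scenario <- function(x, ...) {
  cat("<ecc_scenario>", x$id, "-", x$description, "\n")
  for (e in x$effects) {
    what <- if (!is.null(e$multiplier)) sprintf("x %.4f", e$multiplier) else
      sprintf("set from %s x %g", e$set_from, e$scale)
    cat(sprintf("  %s %s  [ages: %s; risks: %s]\n",
                paste(e$flows, collapse = "+"), what,
                paste(e$ages, collapse = ","), paste(e$risks, collapse = ",")))
  }
  cat("  cost components:", if (length(x$cost_components))
    paste(vapply(x$cost_components, `[[`, "", "model"), collapse = ", ")
    else "none", "\n")
  invisible(x)
}

#' Apply a scenario's rate modifiers
#'
#' Targeted flows are multiplied by their multipliers (or set from a baseline
#' flow) in targeted strata only; untargeted strata and the input object are
#' untouched. `set_from` effects read the unmodified input rates, so effect
#' application is order-independent.
#'
#' @param rates baseline `ecc_rates`.
#' @param scenario an `ecc_scenario` (or `NULL`, returning `rates`).
#' @return A modified copy of `rates`.
#' @export
apply_scenario <- function(rates, scenario) {
  if (is.null(scenario)) return(rates)
  stopifnot(inherits(rates, "ecc_rates"), inherits(scenario, "ecc_scenario"))
  base <- rates
  for (e in scenario$effects) {
    if (is.null(e$set_from)) next
    for (f in e$flows)
      rates$flows[[f]][e$ages, e$risks] <-
        base$flows[[e$set_from]][e$ages, e$risks] * e$scale
  }
  for (e in scenario$effects) {
    if (is.null(e$multiplier)) next
    for (f in e$flows)
      rates$flows[[f]][e$ages, e$risks] <-
        rates$flows[[f]][e$ages, e$risks] * e$multiplier
  }
  rates
}

#' Combine scenarios
#'
#' Multiplier effects on the same flow and stratum compose multiplicatively
#' (independent residual risks); program-cost components concatenate, each
#' costed separately.
#'
#' @param ... `ecc_scenario` objects, or a single list of them.
#' @param id,description label for the combination (default: ids joined
#'   with `+`).
#' @return An `ecc_scenario`.
#' @export
combine_scenarios <- function(..., id = NULL, description = NULL) {
  ss <- list(...)
  if (length(ss) == 1 && !inherits(ss[[1]], "ecc_scenario")) ss <- ss[[1]]
  if (!length(ss)) stop("need at least one scenario", call. = FALSE)
  for (s in ss) stopifnot(inherits(s, "ecc_scenario"))
  ids <- vapply(ss, `[[`, "", "id")
  ecc_scenario(
    id = if (is.null(id)) paste(ids, collapse = "+") else id,
    description = if (is.null(description))
      paste(vapply(ss, `[[`, "", "description"), collapse = " + ")
    else description,
    effects = do.call(c, lapply(ss, `[[`, "effects")),
    cost_components = do.call(c, lapply(ss, `[[`, "cost_components"))
  )
}

#' The catalog of modelled intervention scenarios
#'
#' Twenty scenarios across six program families: community water
#' fluoridation, fluoride varnish, maternal transmission reduction, direct
#' child xylitol, clinical treatment (secondary prevention of white spots and
#' recurrence reduction), motivational interviewing, and combinations.
#' Effect sizes are the published program efficacies; `>6 mo` targeting maps
#' to the toddler+preschool bands and `>24 mo` to the preschool band.
#'
#' @param transmission_onset how the 73% caries reduction accompanying
#'   maternal treatment is applied: `"averted"` (scaled by the fraction of
#'   colonization averted in each age band, the default) or `"all"` (uniform
#'   among all covered children).
#' @return Named list of `ecc_scenario` objects, in table order.
#' @export
scenario_catalog <- function(transmission_onset = c("averted", "all")) {
  transmission_onset <- match.arg(transmission_onset)
  older <- c("toddler", "preschool")          # > 6 months
  varnish_eff <- 1 / 3                        # one-third decay reduction
  vm <- 1 - varnish_eff
  cat <- list()

  cat[["1.1"]] <- ecc_scenario(
    "1.1", "Community water fluoridation for all",
    effects = list(ecc_effect("decay", multiplier = 1 - 0.254 * 0.246)),
    cost_components = list(list(model = "population_wide",
                                coverage_fraction = 0.246,
                                unit_cost_field =
                                  "fluoridation_cost_per_person_year")))
  varnish <- function(id, desc, ages, risks, per_year)
    ecc_scenario(id, desc,
                 effects = list(ecc_effect("decay", multiplier = vm,
                                           ages = ages, risks = risks)),
                 cost_components = list(list(model = "per_application",
                                             ages = ages, risks = risks,
                                             applications_per_year = per_year,
                                             unit_cost_field =
                                               "varnish_application_cost")))
  cat[["1.2"]] <- varnish("1.2", "Fluoride varnish for children >6 mo",
                          older, RISK_LABELS, 2)
  cat[["1.3"]] <- varnish("1.3", "Fluoride varnish for high-risk children >6 mo",
                          older, "high", 3)
  cat[["1.4"]] <- varnish("1.4", "Fluoride varnish for all children >24 mo",
                          "preschool", RISK_LABELS, 2)

  transmission <- function(id, desc, risks) {
    col_red <- c(toddler = 0.88, preschool = 0.64)  # colonization reduction
    onset_mult <- if (transmission_onset == "averted")
      1 - 0.73 * col_red else c(toddler = 0.27, preschool = 0.27)
    ecc_scenario(id, desc,
                 effects = list(
                   ecc_effect("colonization", multiplier = 1 - col_red[["toddler"]],
                              ages = "toddler", risks = risks),
                   ecc_effect("colonization", multiplier = 1 - col_red[["preschool"]],
                              ages = "preschool", risks = risks),
                   ecc_effect("caries_onset", multiplier = onset_mult[["toddler"]],
                              ages = "toddler", risks = risks),
                   ecc_effect("caries_onset", multiplier = onset_mult[["preschool"]],
                              ages = "preschool", risks = risks)),
                 cost_components = list(list(model = "per_mother_once",
                                             risks = risks,
                                             unit_cost_field =
                                               "maternal_xylitol_cost")))
  }
  cat[["2.1"]] <- transmission("2.1", "Xylitol for all mothers", RISK_LABELS)
  cat[["2.2"]] <- transmission("2.2", "Xylitol for mothers of high-risk children",
                               "high")

  xylitol <- function(id, desc, ages, risks, efficacy)
    ecc_scenario(id, desc,
                 effects = list(ecc_effect("decay", multiplier = 1 - efficacy,
                                           ages = ages, risks = risks)),
                 cost_components = list(list(model = "per_child_once",
                                             ages = ages, risks = risks,
                                             unit_cost_field =
                                               "child_xylitol_cost")))
  cat[["3.1"]] <- xylitol("3.1", "Xylitol for all children >24 mo, low-impact",
                          "preschool", RISK_LABELS, 0.44)
  cat[["3.2"]] <- xylitol("3.2", "Xylitol for all children >24 mo, high-impact",
                          "preschool", RISK_LABELS, 0.73)
  cat[["3.3"]] <- xylitol("3.3", "Xylitol for high-risk children >24 mo, low-impact",
                          "preschool", "high", 0.44)
  cat[["3.4"]] <- xylitol("3.4", "Xylitol for high-risk children >24 mo, high-impact",
                          "preschool", "high", 0.73)
  cat[["3.5"]] <- xylitol("3.5", "Xylitol for all children >6 mo, high-impact",
                          older, RISK_LABELS, 0.73)

  caries_treat <- function(id, desc, scale)
    ecc_scenario(id, desc,
                 effects = list(ecc_effect("caries_treatment",
                                           set_from = "treatment_cavity",
                                           scale = scale, ages = older)),
                 cost_components = list(list(model = "per_treatment_episode",
                                             unit_cost_field =
                                               "caries_management_cost")))
  cat[["4.1"]] <- caries_treat("4.1",
    "Caries treatment, children >6 mo, low treatment intensity", 1)
  cat[["4.2"]] <- caries_treat("4.2",
    "Caries treatment, children >6 mo, high treatment intensity", 2)
  cat[["4.3"]] <- ecc_scenario("4.3", "Prevention of recurrence, 50% reduction",
    effects = list(ecc_effect("recurrence", multiplier = 0.5)),
    cost_components = list(list(model = "none")))
  cat[["4.4"]] <- ecc_scenario("4.4", "Prevention of recurrence, 75% reduction",
    effects = list(ecc_effect("recurrence", multiplier = 0.25)),
    cost_components = list(list(model = "none")))

  mi <- function(id, desc, risks)
    ecc_scenario(id, desc,
                 effects = list(ecc_effect("decay", multiplier = 1 - 0.63,
                                           risks = risks)),
                 cost_components = list(list(model = "per_child_once",
                                             ages = AGE_LABELS, risks = risks,
                                             unit_cost_field = "mi_cost")))
  cat[["5.1"]] <- mi("5.1", "Motivational interviewing for all families",
                     RISK_LABELS)
  cat[["5.2"]] <- mi("5.2", "Motivational interviewing for high-risk families only",
                     "high")

  cat[["6.1"]] <- combine_scenarios(cat[["1.2"]], cat[["4.1"]], id = "6.1",
                                    description = "Combination of 1.2 and 4.1")
  cat[["6.2"]] <- combine_scenarios(cat[["1.2"]], cat[["4.1"]], cat[["4.3"]],
                                    id = "6.2",
                                    description = "Combination of 1.2, 4.1, and 4.3")
  cat[["6.3"]] <- combine_scenarios(cat[["1.2"]], cat[["4.1"]], cat[["4.3"]],
                                    cat[["5.1"]], id = "6.3",
                                    description = "Combination of 1.2, 4.1, 4.3, and 5.1")
  cat
}
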