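#' @keywords internal
"_PACKAGE"

## Stratification constants. The state space is (age band x risk band x stage).

AGE_LABELS <- c("infant", "toddler", "preschool")
AGE_RESIDENCE <- c(infant = 6, toddler = 18, preschool = 48) # months in band
RISK_LABELS <- c("low", "moderate", "high")

#' Disease-stage labels
#'
#' The caries natural-history chain: an uncolonized tooth surface acquires a
#' cariogenic biofilm (colonization by S. mutans), demineralizes to a
#' precavity ("white spot") lesion, cavitates, may become symptomatic
#' (dentin/pulp involvement), and may be restored. Children with prior
#' restorations can develop recurrent white-spot lesions
#' (\code{precavity_recurrent}) which re-cavitate; keeping recurrent lesions
#' in a separate stock makes "cavity experience" (ever cavitated) a
#' well-defined count that is structurally unaffected by the recurrence rate.
#'
#' @format Character vector of the seven stage labels, in chain order.
#' @export
ECC_STAGES <- c("uncolonized", "colonized", "precavity",
                "cavity_untreated", "cavity_symptomatic", "cavity_treated",
                "precavity_recurrent")

## stages counted as "cavity experience" (ever had a cavity)
EXPERIENCE_STAGES <- c("cavity_untreated", "cavity_symptomatic",
                       "cavity_treated", "precavity_recurrent")
ACTIVE_CAVITY_STAGES <- c("cavity_untreated", "cavity_symptomatic",
                          "cavity_treated")
UNTREATED_STAGES <- c("cavity_untreated", "cavity_symptomatic")

N_AGE <- 3L
N_RISK <- 3L
N_STAGE <- 7L

stratum_name <- function(age, risk) paste(age, risk, sep = "/")

empty_counts <- function() {
  array(0, dim = c(N_AGE, N_RISK, N_STAGE),
        dimnames = list(age = AGE_LABELS, risk = RISK_LABELS,
                        stage = ECC_STAGES))
}

#' Baseline model parameters
#'
#' Returns the parameter set describing the modelled population: totals,
#' age/risk shares, per-risk caries prevalence, calibration targets, the
#' stage-profile defaults used to construct the baseline state, and cost
#' constants. Defaults encode the Colorado 2009 population of 431,070
#' children younger than 6 years.
#'
#' @param ... named overrides of top-level fields (e.g. \code{total_population}),
#'   or of the nested lists \code{targets}, \code{profile}, \code{costs}
#'   (supplied as lists, merged element-wise).
#' @return An object of class \code{ecc_params}.
#' @examples
#' p <- ecc_params()
#' p$total_population
#' @export
ecc_params <- function(...) {
  p <- list(
    name = "colorado_2009",
    total_population = 431070,
    age_shares  = c(infant = 0.082, toddler = 0.247, preschool = 0.671),
    risk_shares = c(low = 0.508, moderate = 0.178, high = 0.314),
    ## per-risk ECC prevalence pattern (survey-reported, parental recall)
    risk_prevalence = c(low = 0.084, moderate = 0.150, high = 0.186),
    residence_months = AGE_RESIDENCE,
    targets = list(
      overall_cavity_fraction = 0.182,
      untreated_of_cavities   = 0.714,
      symptomatic_of_cavities = 0.12,   # consistent with the 12% anesthesia-care fraction
      total_dft               = 265923,
      ten_year_restorative_cost = 208e6,
      visit_rate_band = c(0.002, 0.05)  # restorative visits per child-month
    ),
    profile = list(
      ## relative cavity prevalence by age band; the preschool value is solved
      ## so the share-weighted mean is 1 (prevalence rises steeply with age,
      ## near zero before tooth eruption completes)
      age_prevalence_multipliers = c(infant = 0.02, toddler = 0.35,
                                     preschool = NA_real_),
      ## fraction of children with detectable S. mutans by age band; the
      ## 19-31 month "window of infection" puts most acquisition in the
      ## toddler band, near-universal colonization by late preschool
      smutans_by_age = c(infant = 0.10, toddler = 0.50, preschool = 0.80),
      ## share of the treated-experienced pool currently carrying a
      ## recurrent white-spot lesion
      recurrent_lesion_share = 0.35,
      ## symptomatic treatment-seeking relative to asymptomatic cavities
      treat_symptomatic_ratio = 2,
      ## decayed+filled teeth attribution: relative weights per stage
      ## (untreated : symptomatic : treated : recurrent) and per age band
      ## (fewer erupted teeth in younger children); one global factor is
      ## calibrated so baseline total DFT matches the target
      dft_stage_weights = c(cavity_untreated = 1, cavity_symptomatic = 1.5,
                            cavity_treated = 2, precavity_recurrent = 2),
      dft_age_weights = c(infant = 0.25, toddler = 0.6, preschool = 1)
    ),
    costs = cost_constants()
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm %in% c("targets", "profile", "costs") && is.list(dots[[nm]])) {
      p[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else p[[nm]] <- dots[[nm]]
  }
  validate_params(structure(p, class = "ecc_params"))
}

validate_params <- function(p) {
  stopifnot(p$total_population >= 0)
  for (fld in c("age_shares", "risk_shares")) {
    s <- p[[fld]]
    if (any(s < 0)) stop(fld, " contains a negative share", call. = FALSE)
    if (abs(sum(s) - 1) > 1e-9)
      stop(fld, " must sum to 1 (got ", format(sum(s)), ")", call. = FALSE)
  }
  if (any(p$risk_prevalence < 0 | p$risk_prevalence > 1))
    stop("risk_prevalence must lie in [0, 1]", call. = FALSE)
  p
}

#' @export
print.ecc_params <- function(x, ...) {
  cat("<ecc_params> ", x$name, "\n", sep = "")
  cat("  population:", format(x$total_population, big.mark = ","),
      "children (0-72 mo)\n")
  cat("  age shares:  ", paste(sprintf("%s %.1f%%", AGE_LABELS,
                                       100 * x$age_shares), collapse = ", "), "\n")
  cat("  risk shares: ", paste(sprintf("%s %.1f%%", RISK_LABELS,
                                       100 * x$risk_shares), collapse = ", "), "\n")
  cat("  baseline cavity fraction target:",
      sprintf("%.1f%%", 100 * x$targets$overall_cavity_fraction), "\n")
  invisible(x)
}

#' Read / write a parameter file
#'
#' Parameter files are YAML with the same structure as [ecc_params()]. The
#' canonical Colorado fixture ships with the package
#' (`system.file("extdata", "colorado_2009.yaml", package = "eccsim")`).
#'
#' @param path file path.
#' @return `read_params()` returns an `ecc_params`; `write_params()` its input,
#'   invisibly.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  for (fld in c("age_shares", "risk_shares", "risk_prevalence"))
    raw[[fld]] <- unlist(raw[[fld]])
  raw$residence_months <- unlist(raw$residence_months)
  raw$targets <- lapply(raw$targets, unlist)
  raw$profile <- lapply(raw$profile, unlist)
  raw$costs <- do.call(cost_constants, as.list(unlist(raw$costs)))
  do.call(ecc_params, raw)
}

#' @rdname read_params
#' @param params an `ecc_params` object.
#' @export
write_params <- function(params, path) {
  namedify <- function(x) {
    if (is.list(x)) lapply(x, namedify)
    else if (!is.null(names(x)) && length(x) > 1) as.list(x)
    else x
  }
  out <- namedify(unclass(params))
  out$costs <- namedify(unclass(params$costs))
  yaml::write_yaml(out, path)
  invisible(params)
}

## age multipliers with the preschool entry solved so the weighted mean is 1
resolve_age_multipliers <- function(params) {
  m <- params$profile$age_prevalence_multipliers
  w <- params$age_shares
  if (is.na(m[["preschool"]]))
    m[["preschool"]] <- (1 - w[["infant"]] * m[["infant"]] -
                           w[["toddler"]] * m[["toddler"]]) / w[["preschool"]]
  if (any(m < 0)) stop("age prevalence multipliers must be nonnegative")
  m
}

## per-risk prevalence rescaled so the risk-share-weighted overall equals the
## baseline target (the survey pattern sets relative risk, the target the level)
effective_risk_prevalence <- function(params) {
  pr <- params$risk_prevalence
  w <- params$risk_shares
  s <- params$targets$overall_cavity_fraction / sum(w * pr)
  pr * s
}
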