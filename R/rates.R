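## Transition-rate parameters: the "valves" of the stock-flow diagram.
## Each disease flow is a 3x3 matrix of monthly per-capita rates (age x risk).

#' Disease-flow names
#'
#' Monthly per-capita flows between disease stages, each a 3 x 3 (age x risk)
#' matrix inside an `ecc_rates` object:
#' \describe{
#'   \item{colonization}{uncolonized -> colonized (S. mutans acquisition)}
#'   \item{caries_onset}{colonized -> precavity (white-spot formation)}
#'   \item{cavitation}{precavity -> cavity_untreated}
#'   \item{recavitation}{precavity_recurrent -> cavity_untreated}
#'   \item{symptomatic}{cavity_untreated -> cavity_symptomatic}
#'   \item{treatment_cavity}{cavity_untreated -> cavity_treated}
#'   \item{treatment_symptomatic}{cavity_symptomatic -> cavity_treated}
#'   \item{caries_treatment}{precavity -> colonized (secondary prevention;
#'     0 at baseline)}
#'   \item{recurrence}{cavity_treated -> precavity_recurrent}
#' }
#' @format Character vector of flow names.
#' @export
ECC_FLOWS <- c("colonization", "caries_onset", "cavitation", "recavitation",
               "symptomatic", "treatment_cavity", "treatment_symptomatic",
               "caries_treatment", "recurrence")

flow_matrix <- function(x = 0) {
  matrix(x, N_AGE, N_RISK, dimnames = list(age = AGE_LABELS,
                                           risk = RISK_LABELS))
}

#' Construct a rate-parameter set
#'
#' @param flows named list of 3 x 3 (age x risk) matrices of monthly rates,
#'   one per entry of [ECC_FLOWS]; missing flows default to 0. Scalars are
#'   recycled to full matrices.
#' @param residence_months months of residence per age band (aging-out rate
#'   is its reciprocal).
#' @param birth_risk_shares allocation of births over risk bands; newborns
#'   enter the infant band uncolonized.
#' @param birth_inflow `NULL` for replacement births (births equal the
#'   aging-out flow each step, holding the total population exactly
#'   constant), or a constant monthly inflow.
#' @param mean_dft 3 x 7 (age x stage) matrix of average decayed+filled teeth
#'   attributed per child; nonzero only in cavity-experienced stages.
#' @return An `ecc_rates` object.
#' @export
ecc_rates <- function(flows = list(), residence_months = AGE_RESIDENCE,
                      birth_risk_shares = c(low = 0.508, moderate = 0.178,
                                            high = 0.314),
                      birth_inflow = NULL, mean_dft = NULL) {
  unknown <- setdiff(names(flows), ECC_FLOWS)
  if (length(unknown))
    stop("unknown flow name(s): ", paste(unknown, collapse = ", "),
         "; valid flows are: ", paste(ECC_FLOWS, collapse = ", "),
         call. = FALSE)
  fl <- stats::setNames(lapply(ECC_FLOWS, function(f) {
    v <- flows[[f]]
    if (is.null(v)) return(flow_matrix(0))
    if (length(v) == 1) return(flow_matrix(v))
    stopifnot(all(dim(v) == c(N_AGE, N_RISK)))
    dimnames(v) <- list(age = AGE_LABELS, risk = RISK_LABELS)
    v
  }), ECC_FLOWS)
  for (f in ECC_FLOWS) {
    if (any(is.na(fl[[f]]))) stop("NaN/NA rate in flow ", f, call. = FALSE)
    if (any(fl[[f]] < 0)) stop("negative rate in flow ", f, call. = FALSE)
  }
  if (is.null(mean_dft))
    mean_dft <- matrix(0, N_AGE, N_STAGE,
                       dimnames = list(age = AGE_LABELS, stage = ECC_STAGES))
  structure(list(flows = fl,
                 residence_months = residence_months,
                 aging = 1 / residence_months,
                 birth_risk_shares = birth_risk_shares,
                 birth_inflow = birth_inflow,
                 mean_dft = mean_dft),
            class = "ecc_rates")
}

#' @export
print.ecc_rates <- function(x, ...) {
  cat("<ecc_rates> monthly per-capita flows (age x risk means):\n")
  for (f in ECC_FLOWS)
    cat(sprintf("  %-22s mean %.4f  max %.4f\n", f, mean(x$flows[[f]]),
                max(x$flows[[f]])))
  cat("  births:", if (is.null(x$birth_inflow)) "replacement (aging-out)" else
    format(x$birth_inflow), "\n")
  invisible(x)
}

## Stage-transition topology: source stage and destination stage per flow
## (destination NA = none). Used by step() and by the linear-operator builder.
FLOW_FROM <- c(colonization = "uncolonized", caries_onset = "colonized",
               cavitation = "precavity", recavitation = "precavity_recurrent",
               symptomatic = "cavity_untreated",
               treatment_cavity = "cavity_untreated",
               treatment_symptomatic = "cavity_symptomatic",
               caries_treatment = "precavity",
               recurrence = "cavity_treated")
FLOW_TO <- c(colonization = "colonized", caries_onset = "precavity",
             cavitation = "cavity_untreated", recavitation = "cavity_untreated",
             symptomatic = "cavity_symptomatic",
             treatment_cavity = "cavity_treated",
             treatment_symptomatic = "cavity_treated",
             caries_treatment = "colonized",
             recurrence = "precavity_recurrent")
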