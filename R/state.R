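## Population state: counts per (age x risk x stage) plus accounting registers.

new_state <- function(counts = empty_counts(), time = 0,
                      cum_restorative_visits = 0, cum_restorative_cost = 0,
                      cum_program_cost = 0) {
  structure(list(counts = counts, time = time,
                 cum_restorative_visits = cum_restorative_visits,
                 cum_restorative_cost = cum_restorative_cost,
                 cum_program_cost = cum_program_cost),
            class = "ecc_state")
}

#' Construct an initial population state
#'
#' Distributes a population total over the (age band x risk band x stage)
#' state space as total x age share x risk share x stage fraction, with zeroed
#' accounting registers and time 0.
#'
#' @param total_population number of children aged 0-72 months.
#' @param age_shares,risk_shares nonnegative shares summing to 1 (named or in
#'   infant/toddler/preschool and low/moderate/high order).
#' @param stage_fractions a 3 x 3 x 7 array of per-stratum stage fractions
#'   (each stratum's fractions summing to 1), dimensions age x risk x stage.
#' @return An `ecc_state`.
#' @examples
#' sf <- array(0, dim = c(3, 3, 7))
#' sf[, , 1] <- 1  # everyone uncolonized
#' st <- make_initial_state(431070,
#'                          c(0.082, 0.247, 0.671),
#'                          c(0.508, 0.178, 0.314), sf)
#' sum(st$counts["infant", , ])  # 431070 * 0.082
#' @export
make_initial_state <- function(total_population, age_shares, risk_shares,
                               stage_fractions) {
  if (length(total_population) != 1 || is.na(total_population) ||
      total_population < 0)
    stop("total_population must be a single nonnegative number", call. = FALSE)
  age_shares <- check_shares(age_shares, AGE_LABELS, "age_shares")
  risk_shares <- check_shares(risk_shares, RISK_LABELS, "risk_shares")
  stopifnot(length(dim(stage_fractions)) == 3,
            all(dim(stage_fractions) == c(N_AGE, N_RISK, N_STAGE)))
  counts <- empty_counts()
  for (a in seq_len(N_AGE)) for (r in seq_len(N_RISK)) {
    f <- stage_fractions[a, r, ]
    if (any(is.na(f)) || any(f < 0))
      stop("negative or missing stage fraction in stratum ",
           stratum_name(AGE_LABELS[a], RISK_LABELS[r]), call. = FALSE)
    if (abs(sum(f) - 1) > 1e-6)
      stop("stage fractions do not sum to 1 in stratum ",
           stratum_name(AGE_LABELS[a], RISK_LABELS[r]),
           " (sum = ", format(sum(f)), ")", call. = FALSE)
    counts[a, r, ] <- total_population * age_shares[a] * risk_shares[r] * f
  }
  new_state(counts)
}

check_shares <- function(s, labels, what) {
  if (length(s) != length(labels)) stop(what, " must have length ",
                                        length(labels), call. = FALSE)
  if (!is.null(names(s))) s <- s[labels]
  if (any(is.na(s))) stop(what, " has missing values", call. = FALSE)
  bad <- which(s < 0)
  if (length(bad))
    stop("negative ", what, " for ", labels[bad[1]], call. = FALSE)
  if (abs(sum(s) - 1) > 1e-9 && sum(s) > 0)
    stop(what, " must sum to 1 (got ", format(sum(s)), ")", call. = FALSE)
  stats::setNames(as.numeric(s), labels)
}

#' Total number of children in a state
#' @param state an `ecc_state`.
#' @export
state_total <- function(state) sum(state$counts)

#' Endpoint metrics of a population state
#'
#' @param state an `ecc_state`.
#' @param rates an `ecc_rates` (supplies the decayed-and-filled-teeth
#'   attribution weights); if `NULL`, `total_dft` is `NA`.
#' @return A list with `fraction_with_cavities` (cavity experience: children
#'   in any untreated, symptomatic, treated or recurrent-lesion stage, over
#'   all children), `fraction_with_active_cavities` (excluding recurrent
#'   lesions, i.e. children whose mouths currently hold a cavitated or
#'   restored lesion), `fraction_untreated_of_cavities` (untreated +
#'   symptomatic over cavity-experienced), `symptomatic_fraction` (of
#'   cavity-experienced), and `total_dft`. All ratios are 0 for an empty
#'   population.
#' @export
ecc_metrics <- function(state, rates = NULL) {
  ct <- state$counts
  total <- sum(ct)
  pool <- sum(ct[, , EXPERIENCE_STAGES])
  frac <- function(num, den) if (den > 0) num / den else 0
  dft <- NA_real_
  if (!is.null(rates)) dft <- sum(rates$mean_dft * apply(ct, c(1, 3), sum))
  list(
    fraction_with_cavities = frac(pool, total),
    fraction_with_active_cavities = frac(sum(ct[, , ACTIVE_CAVITY_STAGES]),
                                         total),
    fraction_untreated_of_cavities = frac(sum(ct[, , UNTREATED_STAGES]), pool),
    symptomatic_fraction = frac(sum(ct[, , "cavity_symptomatic"]), pool),
    total_dft = dft
  )
}

#' @export
print.ecc_state <- function(x, ...) {
  m <- ecc_metrics(x)
  cat("<ecc_state> t =", x$time, "months;",
      format(round(state_total(x)), big.mark = ","), "children\n")
  cat(sprintf("  cavity experience %.1f%%; untreated-of-cavities %.1f%%\n",
              100 * m$fraction_with_cavities,
              100 * m$fraction_untreated_of_cavities))
  cat(sprintf("  cumulative restorative cost $%.1fM; program cost $%.1fM\n",
              x$cum_restorative_cost / 1e6, x$cum_program_cost / 1e6))
  invisible(x)
}

#' @export
as.data.frame.ecc_state <- function(x, ...) {
  g <- expand.grid(age_band = AGE_LABELS, risk_band = RISK_LABELS,
                   stage = ECC_STAGES, stringsAsFactors = FALSE)
  g$count <- as.vector(x$counts)
  g$time_months <- x$time
  g[, c("time_months", "age_band", "risk_band", "stage", "count")]
}
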