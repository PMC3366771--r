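## Reporting: run the scenario catalog, build the endpoint results table,
## summary ranges and time-series comparisons.

#' Summarize a scenario run against the baseline run
#'
#' @param traj scenario `ecc_trajectory`.
#' @param baseline baseline `ecc_trajectory` over the same horizon.
#' @param scenario_id label for the row (defaults to the trajectory's).
#' @return An `ecc_result` with the endpoint metrics, cumulative restorative
#'   cost, restorative savings versus baseline (baseline cost minus scenario
#'   cost), cumulative program cost, and the full trajectory.
#' @export
ecc_summarize <- function(traj, baseline, scenario_id = traj$scenario_id) {
  if (traj$horizon != baseline$horizon)
    stop("scenario and baseline horizons differ", call. = FALSE)
  fin <- endpoint(traj)
  base_fin <- endpoint(baseline)
  m <- ecc_metrics(fin, traj$rates)
  structure(list(
    scenario_id = scenario_id,
    pct_children_with_cavities = 100 * m$fraction_with_cavities,
    pct_cavities_untreated = 100 * m$fraction_untreated_of_cavities,
    dft_total = m$total_dft,
    cum_restorative_cost = fin$cum_restorative_cost,
    restorative_savings_vs_baseline =
      base_fin$cum_restorative_cost - fin$cum_restorative_cost,
    cum_program_cost = fin$cum_program_cost,
    trajectory = traj
  ), class = "ecc_result")
}

#' Run the full scenario catalog
#'
#' One run per catalog scenario from the shared calibrated initial state and
#' rates, plus the no-intervention baseline. Deterministic.
#'
#' @param calibration an `ecc_calibration` (or a list with `rates`, `state`,
#'   `params`).
#' @param horizon months.
#' @param scenarios named list of `ecc_scenario`s (default the full
#'   [scenario_catalog()]).
#' @return An `ecc_table`: list of `ecc_result` rows (baseline first) and
#'   a `failures` list of per-scenario errors, if any.
#' @export
run_catalog <- function(calibration, horizon = 120,
                        scenarios = scenario_catalog()) {
  constants <- calibration$params$costs
  base <- ecc_run(calibration$state, calibration$rates, NULL, horizon,
                  constants = constants)
  rows <- list(baseline = ecc_summarize(base, base, "baseline"))
  failures <- list()
  for (s in scenarios) {
    r <- tryCatch({
      traj <- ecc_run(calibration$state, calibration$rates, s, horizon,
                      constants = constants)
      ecc_summarize(traj, base)
    }, error = function(e) e)
    if (inherits(r, "error")) failures[[s$id]] <- conditionMessage(r)
    else rows[[s$id]] <- r
  }
  structure(list(rows = rows, failures = failures, horizon = horizon),
            class = "ecc_table")
}

#' Results table as a data frame
#'
#' Seven columns mirroring the reported endpoint table. With
#' `rounded = TRUE` percentages are reported to one decimal, teeth counts to
#' whole teeth and dollars to whole millions (half-up); otherwise full
#' precision is kept.
#'
#' @param x an `ecc_table`.
#' @param rounded round to report granularity.
#' @param ... unused.
#' @export
as.data.frame.ecc_table <- function(x, rounded = FALSE, ...) {
  half_up <- function(v, digits = 0) floor(v * 10^digits + 0.5) / 10^digits
  df <- do.call(rbind, lapply(x$rows, function(r) data.frame(
    scenario = r$scenario_id,
    pct_children_with_cavities = r$pct_children_with_cavities,
    pct_cavities_untreated = r$pct_cavities_untreated,
    dft_total = r$dft_total,
    restorative_cost_musd = r$cum_restorative_cost / 1e6,
    savings_musd = r$restorative_savings_vs_baseline / 1e6,
    program_cost_musd = r$cum_program_cost / 1e6,
    stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  if (rounded) {
    df$pct_children_with_cavities <- half_up(df$pct_children_with_cavities, 1)
    df$pct_cavities_untreated <- half_up(df$pct_cavities_untreated, 1)
    df$dft_total <- half_up(df$dft_total)
    for (col in c("restorative_cost_musd", "savings_musd",
                  "program_cost_musd"))
      df[[col]] <- half_up(df[[col]])
  }
  df
}

#' @export
print.ecc_table <- function(x, ...) {
  print(as.data.frame(x, rounded = TRUE))
  if (length(x$failures))
    cat("FAILED scenarios:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}

#' Summary ranges across the intervention rows
#'
#' @param table an `ecc_table`.
#' @return List with the minimum/maximum ten-year program cost and the
#'   minimum/maximum relative reduction in cavity prevalence versus baseline
#'   (`(baseline% - scenario%) / baseline%`), over intervention rows only.
#'   Empty (NA) ranges if the table holds only the baseline row.
#' @export
summary_ranges <- function(table) {
  rows <- table$rows[setdiff(names(table$rows), "baseline")]
  if (!length(rows))
    return(list(program_cost_range_musd = c(NA_real_, NA_real_),
                relative_reduction_range_pct = c(NA_real_, NA_real_)))
  base_pct <- table$rows$baseline$pct_children_with_cavities
  red <- vapply(rows, function(r)
    100 * (base_pct - r$pct_children_with_cavities) / base_pct, 0)
  cost <- vapply(rows, function(r) r$cum_program_cost / 1e6, 0)
  list(program_cost_range_musd = range(cost),
       relative_reduction_range_pct = range(red),
       max_reduction_scenario = names(rows)[which.max(red)])
}

#' Time-series comparison of scenarios against baseline
#'
#' Monthly counts of cavity-experienced children within an age filter, per
#' scenario and for the baseline.
#'
#' @param calibration an `ecc_calibration`.
#' @param scenario_ids catalog ids to compare.
#' @param ages age-band labels to include (default the preschool band,
#'   children aged 25-72 months).
#' @param horizon months.
#' @param scenarios scenario catalog to draw from.
#' @return Data frame with columns `time_months`, `scenario`,
#'   `cavity_experienced`.
#' @export
timeseries_compare <- function(calibration, scenario_ids,
                               ages = "preschool", horizon = 120,
                               scenarios = scenario_catalog()) {
  unknown <- setdiff(scenario_ids, names(scenarios))
  if (length(unknown))
    stop("unknown scenario id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  ages <- match.arg(ages, AGE_LABELS, several.ok = TRUE)
  series <- function(traj, label) {
    data.frame(time_months = vapply(traj$states, `[[`, 0, "time"),
               scenario = label,
               cavity_experienced = vapply(traj$states, function(s)
                 sum(s$counts[ages, , EXPERIENCE_STAGES]), 0),
               stringsAsFactors = FALSE)
  }
  out <- series(ecc_run(calibration$state, calibration$rates, NULL, horizon,
                        constants = calibration$params$costs), "baseline")
  for (id in scenario_ids)
    out <- rbind(out, series(
      ecc_run(calibration$state, calibration$rates, scenarios[[id]], horizon,
              constants = calibration$params$costs), id))
  out
}

#' Plot a time-series comparison
#'
#' @param ts data frame from [timeseries_compare()].
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_timeseries <- function(ts) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_timeseries requires ggplot2", call. = FALSE)
  ggplot2::ggplot(ts, ggplot2::aes(x = .data$time_months,
                                   y = .data$cavity_experienced,
                                   colour = .data$scenario)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Months", y = "Children with cavity experience",
                  colour = "Scenario") +
    ggplot2::theme_minimal()
}
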