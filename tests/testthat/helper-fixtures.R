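# Shared fixtures, computed once per test session.

.fixture_env <- new.env(parent = emptyenv())

# Calibrated baseline (seed 17, full refinement) — the expensive shared object.
cached_cal <- function() {
  if (is.null(.fixture_env$cal))
    .fixture_env$cal <- suppressWarnings(ecc_calibrate(ecc_params(), seed = 17))
  .fixture_env$cal
}

# Full 21-row endpoint table from the cached calibration.
cached_table <- function() {
  if (is.null(.fixture_env$tab))
    .fixture_env$tab <- run_catalog(cached_cal())
  .fixture_env$tab
}

# Stage-fraction array with all mass in one stage.
one_stage_fractions <- function(stage = "uncolonized") {
  sf <- array(0, dim = c(3, 3, 7),
              dimnames = list(age = c("infant", "toddler", "preschool"),
                              risk = c("low", "moderate", "high"),
                              stage = ECC_STAGES))
  sf[, , stage] <- 1
  sf
}

# A single-stratum-style state: `n` children per stratum in one stage,
# with aging and births switched off via infinite residence.
still_rates <- function(flows = list()) {
  ecc_rates(flows, residence_months = c(Inf, Inf, Inf))
}

pct_cavities <- function(result) result$pct_children_with_cavities
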