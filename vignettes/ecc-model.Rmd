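---
title: "Modelling early childhood caries: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling early childhood caries: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eccsim)
```

## The model

`eccsim` is a compartmental stock-flow ("system dynamics") model of early
childhood caries in a standing population of children aged 0–72 months,
stratified into 3 age bands × 3 risk bands × 7 disease stages = 63 stocks.
Disease flows are first-order: each month a fixed fraction of a stock moves
along the natural-history chain (colonization by cariogenic bacteria,
white-spot formation, cavitation, symptom development, restorative
treatment, recurrence). Aging is a first-order chain with outflow
1/residence per band (6, 18, 48 months), the standard system-dynamics aging
approximation; it smears cohorts exponentially rather than tracking them,
which is accepted here because every reported quantity is a population
aggregate. Births replace preschool age-outs exactly (entering uncolonized,
split by the population risk shares), so total population is conserved to
machine precision; a constant birth inflow can be supplied instead, at the
cost of a small demographic transient.

### Why a seventh stage

Recurrence — new caries activity in children with prior repair — is modelled
as `cavity_treated → precavity_recurrent → cavity_untreated`, with the
recurrent white-spot stock kept separate from never-cavitated precavity. Two
reasons. First, semantics: "children with cavities" is a cavity-*experience*
measure, and a treated child who develops a new white spot has not stopped
being cavity-experienced. With a separate stock, cavity experience
(`cavity_untreated + cavity_symptomatic + cavity_treated +
precavity_recurrent`) is structurally invariant to the recurrence rate —
recurrence only cycles children *within* the experienced pool — which is
exactly the behaviour recurrence-prevention programs show: they change the
untreated share and the repair bill, never the prevalence of experience. In
a six-stage chain where recurrence feeds the ordinary precavity stock this
invariance is algebraically impossible (the recurrence flow removes children
from the experienced pool and the precavity balance depends on it). Second,
rates: recurrent lesions sit in restored, previously affected mouths and
progress much faster than first lesions; the calibration gives them their
own cavitation rate (`recavitation`), solved from the treated-pool balance.
Tying recurrent lesions to the primary cavitation rate is not merely
inaccurate but infeasible: the treated+recurrent pool implied by the
baseline cost and untreated-share targets cannot absorb the recurrence flux
at the primary (slow) rate.

Both prevalence definitions are exposed: `ecc_metrics()` reports cavity
experience and the stricter "active cavity" fraction
(untreated + symptomatic + treated only).

## Baseline construction

The calibrated baseline is built from population summaries, all carried in
`ecc_params()`:

* **Level and pattern of prevalence.** The survey-reported per-risk
  prevalences (8.4 / 15.0 / 18.6% for low / moderate / high risk) weighted
  by the risk shares give 12.8%, while the examination-adjusted overall
  baseline is 18.2% — parental report misses nonsymptomatic cavities. The
  survey values are therefore used as the *relative* risk pattern and
  rescaled by a single factor (1.4244) so the weighted overall equals 18.2%.
* **Age gradient.** Cavity experience by age is the per-risk level times an
  age multiplier profile (0.02, 0.35, solved-to-normalize ≈ 1.36): near zero
  before teeth fully erupt, steeply rising through the preschool years.
  These two multipliers are the model's guess at an age gradient the
  summaries do not print; they were fixed once, a priori.
* **Precavity pipeline.** `age_extrapolate_precavity()` backward-extrapolates
  the between-band increase in cavity prevalence: the children who will
  convert within one band-residence are currently carrying white spots, so
  band *a*'s precavity fraction is the inter-band increment scaled by
  residence(a)/residence(a+1), the oldest band using its own incoming
  increment.
* **Within-pool split.** Of cavity-experienced children, 71.4% are untreated
  (including 12% symptomatic — chosen consistent with the 12% of treated
  children needing general anesthesia) and 28.6% treated-or-recurrent, with
  35% of that remainder currently carrying a recurrent lesion
  (`recurrent_lesion_share`, a structural default).
* **Colonization.** Detectable cariogenic (S. mutans) colonization by age is
  set to 10 / 50 / 80%, flat across risk bands: acquisition concentrates in
  the 19–31-month "window of infection" and is near-universal by late
  preschool. The risk gradient of disease is carried by the progression
  rates, not by colonization prevalence.

## Calibration

With the target state fixed, stationarity is a system of per-stratum
balance equations, and because aging-in flows depend only on the (known)
target stocks of the next-younger band, the equations solve *explicitly*,
stratum by stratum, from the symptomatic balance upward to colonization.
The restorative treatment level is set first: the ten-year cost target
divided by 120 months and the blended episode cost ($1,107.36) gives the
monthly visit flow; symptomatic children seek treatment at twice the
asymptomatic rate (`treat_symptomatic_ratio`, default 2). One corrective
pass rescales the flow so the *simulated* — not just instantaneous —
ten-year cost matches.

The algebraic solution is then polished by bounded trust-region least
squares (`minpack.lm::nls.lm`) over one log-multiplier per flow family
(bounds ×0.25–×4), minimizing squared relative residuals of the 120-month
endpoint metrics, a restorative-visit-rate band penalty, and the one-step
stationarity residual weighted 10× (the model is *defined* as holding the
initial distribution). Eight seeded starting points (the algebraic solution
plus seven jittered copies) make the result deterministic given the seed.
The per-family parameterisation deliberately under-parameterises: with more
free rates than observable targets the full 63-rate system is not
identifiable, so calibration is validated as *metric* recovery — rebuilding
targets from a known-rate equilibrium and recovering its metrics to within
1% — never as rate recovery.

Decayed-and-filled-teeth attribution is separable: per-stage weights
(untreated 1 : symptomatic 1.5 : treated 2 : recurrent 2) times per-age
weights (0.25 / 0.6 / 1, fewer erupted teeth in younger children), with one
global factor fixed so the baseline carries exactly the target 265,923
teeth.

## Numerical choices

* Explicit Euler with dt = 1 month; every rate × dt must be ≤ 1 and a stock
  driven below −10⁻⁶ aborts with advice to shrink dt. Calibrated rates are
  capped at 0.9/month. Stocks are continuous; counts are rounded (half-up)
  only at reporting time, percentages to one decimal and dollars to whole
  millions in the endpoint table.
* The baseline system is linear in the stocks (replacement births included),
  so the calibration loss advances the state by a cached 63 × 63 one-step
  matrix rather than the array stepper; the two paths agree to ~10⁻¹⁰ and
  the matrix exponential of the same generator serves as an independent
  closed-form oracle in the tests (2% per-stock agreement for stocks of at
  least 10 children; sub-child stocks are compared absolutely, at 0.5
  children, since relative error on a two-child stock is noise).
* The printed age shares (8.2 / 24.7 / 67.1%) are not the fixed point of the
  1/6–1/18–1/48 aging chain (8.33 / 25 / 66.67%), so exact stationarity is
  unattainable by construction; the residual demographic drift moves the
  baseline prevalence by under 0.1 percentage points over ten years. The
  stationarity residual is reported as the one-step L2 change of the state
  vector relative to total population.
* Metrics of an empty population are defined as 0; degenerate strata
  (near-zero source stocks) get zero rates rather than 0/0.
* Restorative visit-rate band default 0.002–0.05 visits per child-month.
  The survey range behind it is cited but unprinted; the lower default is
  set to contain the visit rate implied by the $208M cost target (0.0036),
  which governs.

## Scenario engine choices

* Fluoride-type agents (fluoridation, varnish) and behavioral efficacy
  (xylitol, motivational interviewing) act on the demineralization flows —
  caries onset and (re)cavitation — because that is the process the agents
  slow; treatment flows are untouched. Varnish frequency (2× vs 3×/yr)
  affects cost, not efficacy, which is a program-level estimate.
* Maternal transmission programs multiply colonization by 0.12 (7–24 mo) and
  0.36 (25–72 mo); the accompanying 73% caries-onset reduction is applied
  scaled by the averted-colonization fraction per band (the "averted"
  reading; a uniform-application alternative is available via
  `scenario_catalog(transmission_onset = "all")`).
* Combinations multiply residual risks (independence); "aggressive"
  secondary prevention treats white spots at 2× the cavity-treatment rate
  (a configurable reading of an otherwise unquantified label). Interventions
  take full effect at t = 0 — the multi-year lag of infant-targeted programs
  emerges from the dynamics, not from dosing schedules.
* Per-child one-time program costs charge the initially eligible stock at
  program start plus each child crossing the eligibility age thereafter;
  per-mother costs follow each entering birth cohort. Eligibility counts
  children in targeted strata regardless of disease stage — public-health
  programs are population-, not diagnosis-, targeted. No cost discounting
  anywhere: reported dollars are plain ten-year sums.

## What the generated baseline does and does not emulate

The constructed baseline emulates a *stationary* mixed-age population with
the printed size, age/risk structure, prevalence pattern, untreated share,
tooth burden and restorative spending. It does not emulate: secular trends
or seasonality; risk-band migration (children never change risk group);
children older than 72 months (benefits accruing to them are outside the
model); per-tooth or per-surface detail (DFT is an attributed average); or
behavioral heterogeneity in program uptake (coverage enters as a scalar).
Passing tests therefore show internal consistency with the printed
summaries, not validity for any particular real population.

## Known limitations

* Scenario endpoints driven by flows the summaries do not pin down inherit
  the model's internal rate structure. In particular, programs restricted to
  children over 24 months come out a few points *more* effective here than
  in the published comparison table — this model places more of the
  cavitation flux in the preschool band — and cumulative restorative savings
  of mild interventions accrue with a ~1–2 year lag through the precavity
  pipeline, so ten-year savings fall short of the end-state reduction times
  ten years.
* Under recurrence-prevention scenarios the DFT total moves a few percent
  (the within-pool composition shifts between stages with different
  attributed tooth burdens) even though cavity experience is exactly
  unchanged.
* The problem sizes used throughout — a 431,070-child population, 63 stocks,
  120 monthly steps, 8 calibration multistarts — keep a full calibration at
  ~5 seconds and the whole 21-run catalog under half a minute on one core.

## A minimal session

```{r, eval = FALSE}
params <- ecc_params()
cal <- ecc_calibrate(params, seed = 17)
cal$converged
tab <- run_catalog(cal)
as.data.frame(tab, rounded = TRUE)
summary_ranges(tab)
```
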