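# eccsim

A system-dynamics simulator of **early childhood caries (ECC)** — tooth decay
in children younger than 6 years — built to compare the ten-year disease and
cost consequences of public-health and clinical interventions in a standing
preschool population.

## Who it is for

Policy analysts and oral-health program planners who need to rank
interventions (community water fluoridation, fluoride varnish, maternal
transmission reduction, child xylitol, secondary prevention of white-spot
lesions, recurrence control, motivational interviewing, and combinations)
by long-run prevalence reduction, restorative-cost offsets and program cost
— using only population summaries that health departments routinely hold.

## The model

The population is stratified by **age band** a (0–6, 7–24, 25–72 months),
**caries risk** r (low / moderate / high, proxied by household income) and
**disease stage** s along the caries natural history:

```
uncolonized → colonized → precavity → cavity_untreated → cavity_symptomatic
                 ↑____________                 ↘︎____________↙
                 (secondary                  cavity_treated
                  prevention)                       ↓ recurrence
                              precavity_recurrent ──→ cavity_untreated
```

Stocks N(a, r, s) evolve by explicit-Euler stock-flow balance with monthly
step dt:

    N(t + dt) = N(t) + dt · [ inflows − (λ_out + μ_a) · N(t) ]

where λ_out are the per-capita disease-flow rates (the "valves" of the flow
diagram) and μ_a = 1/residence_a is the first-order aging outflow (6, 18, 48
months per band). Births replace the children aging out of the preschool
band, entering the infant band uncolonized, split over risk bands by the
population risk shares — so the 431,070-child population is exactly
conserved.

**Calibration.** The transition rates are not observable; they are fitted so
that the no-intervention model *holds the observed baseline as a stationary
state*: 18.2% of children with cavity experience (per-risk pattern
18.6/15.0/8.4%), 71.4% of cavities untreated, 265,923 decayed+filled teeth,
and $208M of restorative care per decade at a blended episode cost of
0.88 × $276 + 0.12 × $7,204 = $1,107.36 (12% of treated children need care
under general anesthesia). `ecc_calibrate()` solves the stage-balance
equations algebraically at the target state, then polishes per-flow
multipliers with bounded trust-region least squares (seeded multistarts;
deterministic).

**Interventions** are declarative rate modifiers: each scenario multiplies
named flows by `1 − efficacy × coverage` in targeted (age × risk) strata
(e.g. fluoridation: 1 − 0.254 × 0.246 on the demineralization flows;
motivational interviewing: 0.37), switches flows on (white-spot treatment at
the cavity-treatment rate), or damps recurrence. Combinations compose
multiplicatively. Each scenario carries a program-cost model
(per application, per child, per mother, per treated episode, or
population-wide).

## Worked example

```r
library(eccsim)

params <- ecc_params()                      # Colorado 2009 fixture
cal <- ecc_calibrate(params, seed = 17)     # ~5 s
tab <- run_catalog(cal, horizon = 120)      # baseline + 20 scenarios
as.data.frame(tab, rounded = TRUE)
```

Selected rows of the printed output (percent of children with cavity
experience, percent of those untreated, total decayed+filled teeth, ten-year
restorative cost, savings versus baseline, and program cost, both in $M):

```
 scenario  pct_cavities  pct_untreated  dft_total  restorative  savings  program
 baseline          18.2           71.4    265,953          208        0        0
      1.1          17.2           71.0    251,575          198       10        6
      1.2          12.5           68.5    187,510          156       52      126
      2.1           8.7           70.6    128,761          148       60       72
      4.3          18.2           64.2    279,348          190       18        0
      5.1           6.6           62.5    103,786          103      105      115
      6.3           3.5           50.2     59,497           71      137      261
```

Reading it: the calibrated baseline holds the observed 18.2% / 71.4% /
265,923-teeth structure for the full decade. Water fluoridation (1.1) buys a
modest reduction for $6M; varnish for everyone over 6 months (1.2) cuts
prevalence by a third; treating mothers (2.1) is slower but stronger by year
ten; recurrence control (4.3) cannot change who *gets* cavities (18.2%
unchanged — recurrent children are already cavity-experienced) but shrinks
the untreated share and the repair bill; the full combination (6.3) cuts
prevalence by about 80%. A time-series view of the varnish-versus-mothers
trade-off:

```r
ts <- timeseries_compare(cal, c("1.2", "2.1"), ages = "preschool")
plot_timeseries(ts)   # varnish wins early, transmission control by year 10
```

A command-line shim wraps the same functions:

```sh
Rscript inst/cli/eccsim.R table --seed 17 --out results.csv
Rscript inst/cli/eccsim.R timeseries --scenarios 1.2,2.1 --out ts.csv
```

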