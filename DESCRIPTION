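Package: eccsim
Title: System-Dynamics Simulation of Early Childhood Caries Interventions
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A compartmental stock-flow simulator of early childhood caries
    (ECC) in a preschool population, stratified by age band, caries risk and
    disease stage. Transition rates are calibrated so that the no-intervention
    model holds a printed baseline prevalence structure as a stationary state;
    a declarative scenario engine encodes preventive and clinical interventions
    as rate modifiers with per-program cost models, and a reporting layer
    regenerates ten-year endpoint tables, cost offsets and time-series
    comparisons for single and combined interventions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
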