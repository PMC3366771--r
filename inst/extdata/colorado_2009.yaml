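name: colorado_2009
total_population: 431070.0
age_shares:
  infant: 0.082
  toddler: 0.247
  preschool: 0.671
risk_shares:
  low: 0.508
  moderate: 0.178
  high: 0.314
risk_prevalence:
  low: 0.084
  moderate: 0.15
  high: 0.186
residence_months:
  infant: 6.0
  toddler: 18.0
  preschool: 48.0
targets:
  overall_cavity_fraction: 0.182
  untreated_of_cavities: 0.714
  symptomatic_of_cavities: 0.12
  total_dft: 265923.0
  ten_year_restorative_cost: 2.08e+08
  visit_rate_band:
  - 0.002
  - 0.05
profile:
  age_prevalence_multipliers:
    infant: 0.02
    toddler: 0.35
    preschool: .na.real
  smutans_by_age:
    infant: 0.1
    toddler: 0.5
    preschool: 0.8
  recurrent_lesion_share: 0.35
  treat_symptomatic_ratio: 2.0
  dft_stage_weights:
    cavity_untreated: 1.0
    cavity_symptomatic: 1.5
    cavity_treated: 2.0
    precavity_recurrent: 2.0
  dft_age_weights:
    infant: 0.25
    toddler: 0.6
    preschool: 1.0
costs:
  office_restorative_cost: 276.0
  ga_episode_cost: 7204.0
  ga_fraction: 0.12
  varnish_application_cost: 16.0
  maternal_xylitol_cost: 100.0
  child_xylitol_cost: 100.0
  mi_cost: 100.0
  caries_management_cost: 242.0
  fluoridation_cost_per_person_year: 0.5
  state_total_population_all_ages: 5024748.0
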