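# Primary prevention model configuration. Same layout as pp15.yaml; mortality
# causes follow the primary-prevention meta-analysis cause breakdown.
population: PP
mortality_icd:
  causes: [sudden_cardiac, heart_failure, other_cardiac, non_cardiac]
  sudden_cardiac: {value: 0.0015, se: 0.0001,  dist: beta}
  heart_failure:  {value: 0.0029, se: 0.0002,  dist: beta}
  other_cardiac:  {value: 0.0004, se: 0.00002, dist: beta}
  non_cardiac:    {value: 0.0024, se: 0.0002,  dist: beta}
mortality_no_icd:
  causes: [sudden_cardiac, heart_failure, other_cardiac, non_cardiac]
  sudden_cardiac: {value: 0.0042, se: 0.0004,  dist: beta}
  heart_failure:  {value: 0.0029, se: 0.0003,  dist: beta}
  other_cardiac:  {value: 0.0002, se: 0.00002, dist: beta}
  non_cardiac:    {value: 0.0031, se: 0.0003,  dist: beta}
events:
  operative_death_initial:      {value: 0.0002, se: 0.00002, dist: beta, basis: per_implant}
  shock_continue:               {value: 0.0034, se: 0.0002,  dist: beta, basis: monthly}
  shock_discontinue:            {value: 0.0001, se: 0.00007, dist: beta, basis: monthly}
  lead_replacement_initial:     {value: 0.0004, se: 0.0005,  dist: beta, basis: monthly}
  lead_replacement_replacement: {value: 0.0008, se: 0.0009,  dist: beta, basis: monthly}
  lead_dislodgement_initial:    {value: 0.018,  se: 0.0012,  dist: beta, basis: annual}
  lead_dislodgement_replacement: {value: 0.005, se: 0.0009,  dist: beta, basis: annual}
  infection_initial:            {value: 0.0244, se: 0.0049,  dist: beta, basis: phase_lifetime}
  infection_replacement:        {value: 0.0432, se: 0.0064,  dist: beta, basis: phase_lifetime}
costs:
  implant_initial: 633678
  implant_replacement: 315513
  lead_replacement: 62757
  infection: 765213
  lead_dislodgement: 61566
  generator_removal: 64290
  inappropriate_shock: 670
  monthly_inpatient: 6828
  monthly_outpatient: 858
utilities:
  annual_utility_well:        {value: 0.7315, se: 0.0126, dist: beta}
  utility_complication_state: {value: 0.6474, se: 0.112,  dist: beta}
  complication_decrement: 0.096
  complication_decrement_duration_days: 3.5
structural:
  horizon_months: 420
  annual_discount_rate: 0.01375
  cohort_size: 1000
  device_replacement_interval_months: 96
  wtp_threshold: 2100000
  apply_operative_death_at_replacement: false
  half_cycle_correction: false
  background_mortality_mode: excess
  entry_age_years: 61.1
  life_table: life_table_taiwan_synthetic.csv
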