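# One-way sensitivity axes. Scale axes (@scale) multiply every value in the
# named block; ranges without a published counterpart default to +/-20%
# (utility upper bound capped so the annual utility stays below 1).
axes:
  - label: Age at implant
    parameter: structural.entry_age_years
    low: 51.1
    high: 71.1
  - label: Conventional mortality
    parameter: mortality_no_icd.@scale
    low: 0.8
    high: 1.2
  - label: Replacement period
    parameter: structural.device_replacement_interval_months
    low: 48
    high: 120
  - label: Quality of life
    parameter: utilities.@scale
    low: 0.8
    high: 1.15
  - label: Event costs
    parameter: costs.@scale
    low: 0.8
    high: 1.2
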