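# Default pipeline configuration: per-unit calibrations are read from the
# packaged calibrations.yaml; discordance thresholds, daily completeness and
# exclusion windows follow the Armidale collocation analysis.
conversions:
  - woodsmoke
  - alt34
qc:
  ad_abs_threshold: 10
  ad_frac_threshold: 0.5
min_hours: 23
exclusions:
  - label: black_summer_bushfires
    start: 2019-11-01
    end: 2020-01-31
  - label: teom_data_problem
    start: 2022-01-01
    end: 2022-05-31
periods:
  - all
  - apr_sep
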