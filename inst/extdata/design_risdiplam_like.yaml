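# Bundled synthetic trial design emulating the structure of the case study:
# 525 subjects in total (382 paediatric aged 2 months-18 years plus 143
# adults to 61 years), weight-based once-daily oral dosing in the young,
# sparse steady-state sampling (2-4 samples per visit over 3 visits). The
# visit schedule and arm sizes are representative, not a replica of any
# real trial.

name: risdiplam_like_case
regimen:
  interval_h: 24        # once daily, sampled at steady state
visits_days: [14, 112, 365]
samples_per_visit: [2, 4]
sampling_window_h: [0.5, 24]
bsv:                    # log-normal between-subject variability (SD of log)
  CL_int: 0.30
  V: 0.20
residual:
  prop: 0.15            # proportional residual CV
  add: 0.1              # additive residual SD, ng/mL
weight_cv: 0.15
arms:
  - {age_range: [0.167, 2.0], n_subjects: 100, dose: {type: mg_per_kg, value: 0.20}, age_dist: log_uniform}
  - {age_range: [2.0, 6.0],   n_subjects: 100, dose: {type: mg_per_kg, value: 0.25, cap_mg: 5}}
  - {age_range: [6.0, 12.0],  n_subjects: 100, dose: {type: mg_per_kg, value: 0.25, cap_mg: 5}}
  - {age_range: [12.0, 18.0], n_subjects: 82,  dose: {type: mg_per_kg, value: 0.25, cap_mg: 5}}
  - {age_range: [18.0, 61.0], n_subjects: 143, dose: {type: fixed_mg, value: 5}}
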