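# Example analysis configuration. Every entry is optional; the values below
# are the package defaults, shown for reference.
column_map:
  participant_id: participant_id
  test: test_name
  hand: hand
  timestamp: test_date
  metric: metric_name
  value: metric_value
  sdmt_baseline: sdmt_baseline
  age: age_years
metric_map:
  e-SDMT: correct_responses
  FingerPinching: successful_pinches
  DrawAShape: shapes_correct
  TwoMinuteWalk: steps
  UTurn: turn_speed
  StaticBalance: sway_path
cutoff_date: "2021-07-31"
min_reps: 5
min_weeks: 5
time_axis: repetition
n_boot: 1000
sim:
  test: e-SDMT
  n_units: 262
  mu_y0: 41.0
  mu_boundary: 57.7
  sd_y0: 10
  sd_boundary: 10
  sigma_resid: 3.3
  reps_median: 11
  reps_iqr: 11
  reps_max: 119
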