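seed: 20260101
cohort:
  n_subjects: 40
  class_fractions:
    normal: 0.2
    prehypertension: 0.37
    stage1: 0.26
    stage2: 0.18
protocol:
  conditions:
  - static
  - warm_rest
  - cold_walk
  - rest
  lead_in_s: 90.0
  obs_spacing_s: 90.0
  obs_per_condition: 3
bp_modulation:
  sbp_offset:
    static: 0.0
    warm_rest: -10.0
    cold_walk: 15.0
    rest: -4.0
  dbp_offset:
    static: 0.0
    warm_rest: -6.0
    cold_walk: 10.0
    rest: -3.0
  subject_sd: 3.0
  observation_sd: 3.0
signals:
  fs:
    ecg: 500.0
    pcg: 500.0
    imp: 50.0
    activity: 25.0
  hrv_sd_s: 0.01
  ecg_noise_sd: 0.0
  pcg_noise_sd: 0.0
  imp_noise_sd: 0.0
  cardiac_ripple_ohm: 0.02
  movement_epochs_per_session: 1
  movement_duration_s: 20.0
  movement_amplitude: 3.0
coupling:
  enabled: yes
  r_to_s2_intercept_s: 0.4
  r_to_s2_slope_s_per_mmhg: -0.001
  r_to_s2_jitter_sd_s: 0.002
  s1s2_ratio_intercept: 1.5
  s1s2_ratio_slope_per_mmhg: 0.01
  s1s2_ratio_jitter_sd: 0.02
  resp_rate_slope_per_mmhg: 0.02
observers:
  noise_sd_mmhg: 2.0
  cuff_bias_mmhg: 3.0
  cuff_noise_sd_mmhg: 5.0
  cuff_delay_s: 60.0
quality:
  saturation_rail:
    ecg1: 5.0
    ecg2: 5.0
    pcg: 5.0
    imp1: 60.0
    imp2: 60.0
  saturation_run: 50
  variance_floor: 1.0e-10
  movement_threshold: 0.5
  rr_range_s:
  - 0.3
  - 2.0
window:
  mode: preceding
  lookback_s: 300.0
  window_s: 60.0
features:
  band_low_hz:
  - 20.0
  - 50.0
  band_mid_hz:
  - 50.0
  - 100.0
  band_high_hz:
  - 100.0
  - 240.0
  s1_window_s: 0.04
  resp_band_hz:
  - 0.07
  - 1.0
  max_missing_fraction: 0.3333333
split:
  fraction: 0.8
  by_subject: no
selection:
  threshold: 0.02
  num_trees: 500
  per_target: yes
model:
  rf_num_trees: 300
  xgb_nrounds: 150
  xgb_eta: 0.05
  xgb_max_depth: 4
  bag_n: 20
bootstrap:
  n_comparison: 10000
  n_mad: 1000
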