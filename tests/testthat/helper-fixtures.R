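# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# config for noise-free waveform synthesis (HRV off, no movement epochs)
noise_free_config <- function(n_subjects = 4) {
  cfg <- default_config(n_subjects = n_subjects)
  cfg$signals$hrv_sd_s <- 0
  cfg$signals$movement_epochs_per_session <- 0L
  cfg$seed <- 7L
  validate_config(cfg)
}

# one noise-free full session (subject + recording + ground truth)
noise_free_session <- function() {
  if (!exists("session", .fixtures)) {
    cfg <- noise_free_config()
    cohort <- generate_cohort(4, c(normal = .25, prehypertension = .25,
                                   stage1 = .25, stage2 = .25), seed = 2)
    .fixtures$session_cfg <- cfg
    .fixtures$session_subject <- cohort[1, ]
    .fixtures$session <- synthesize_recording(cohort[1, ], cfg, seed = 11)
  }
  list(cfg = .fixtures$session_cfg, subject = .fixtures$session_subject,
       ses = .fixtures$session)
}

# standalone clean synthetic ECG: Gaussian P-QRS-T train at constant RR
make_ecg <- function(hr = 60, dur = 60, fs = 500, qrs = 0.10, first_beat = 0.5) {
  r_times <- seq(first_beat, dur - 0.5, by = 60 / hr)
  t <- (seq_len(round(dur * fs)) - 1) / fs
  x <- numeric(length(t))
  sg <- qrs / (2 * sqrt(2 * log(10)))
  for (r in r_times) {
    x <- x + 0.15 * exp(-0.5 * ((t - r + 0.16) / 0.02)^2) +
      1.0 * exp(-0.5 * ((t - r) / sg)^2) +
      0.30 * exp(-0.5 * ((t - r - 0.25) / 0.05)^2)
  }
  list(x = x, fs = fs, r_times = r_times)
}

# standalone PCG ensemble beat with planted S1/S2 bursts
make_pcg_beat <- function(fs = 500, rr = 1.0, s1 = 0.04, s2 = 0.30,
                          a1 = 1.0, a2 = 0.7, r_frac = 0.2) {
  pre <- round(r_frac * rr * fs)
  n <- round(rr * fs)
  tt <- (seq_len(n) - pre - 1) / fs   # time relative to R
  beat <- a1 * exp(-0.5 * ((tt - s1) / 0.01)^2) * cos(2 * pi * 35 * (tt - s1)) +
    a2 * exp(-0.5 * ((tt - s2) / 0.01)^2) * cos(2 * pi * 55 * (tt - s2))
  structure(list(beat = beat, fs = fs, r_index = pre + 1L, median_rr = rr,
                 n_beats_averaged = 10L, mode = "pcg"),
            class = "ensemble_beat")
}

# tiny fast pipeline config (feature-level scale, short sessions)
tiny_pipeline_config <- function(seed = 5L) {
  cfg <- default_config(n_subjects = 10)
  cfg$protocol$obs_per_condition <- 2L
  cfg$selection$num_trees <- 200L
  cfg$model$rf_num_trees <- 100L
  cfg$model$xgb_nrounds <- 50L
  cfg$model$bag_n <- 8L
  cfg$bootstrap$n_comparison <- 2000L
  cfg$bootstrap$n_mad <- 500L
  cfg$seed <- as.integer(seed)
  validate_config(cfg)
}
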