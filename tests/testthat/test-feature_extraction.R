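test_that("R peaks on clean ECG are recovered at the planted samples", {
  fx <- make_ecg(hr = 60, dur = 60)
  ann <- detect_r_peaks(fx$x, fx$fs)
  expect_true(abs(length(ann$r_times) - 60) <= 1)
  err <- vapply(ann$r_times, function(t) min(abs(t - fx$r_times)), numeric(1))
  expect_lte(max(err) * fx$fs, 1)                 # within one sample
  expect_equal(ann$mean_interbeat_interval, 1.0, tolerance = 1e-3)
  expect_error(detect_r_peaks(numeric(30 * 500), 500), "flat|beats")
})

test_that("R detection survives additive white noise at 10 dB SNR", {
  recovered <- 0L; total <- 0L
  for (s in 1:20) {
    fx <- make_ecg(hr = 72, dur = 60)
    set.seed(s)
    snr_sd <- sqrt(mean(fx$x^2) / 10)             # 10 dB SNR
    noisy <- fx$x + rnorm(length(fx$x), 0, snr_sd)
    r <- detect_r_peak_times(noisy, fx$fs)
    hits <- vapply(fx$r_times, function(t) any(abs(r - t) * fx$fs <= 2),
                   logical(1))
    recovered <- recovered + sum(hits); total <- total + length(hits)
  }
  expect_gte(recovered / total, 0.99)
})

test_that("ensemble averaging reduces noise and rejects corrupted beats", {
  fs <- 500
  fx <- make_ecg(hr = 60, dur = 62)
  ann <- detect_r_peaks(fx$x, fs)
  # identical beats: ensemble equals any single beat
  ens <- ensemble_average(fx$x, fs, ann$r_times, "ecg")
  ri <- round(ann$r_times[3] * fs) + 1L
  single <- fx$x[(ri - ens$r_index + 1):(ri + length(ens$beat) - ens$r_index)]
  expect_equal(ens$beat, single, tolerance = 1e-8)

  # zero-mean iid noise shrinks as sigma/sqrt(n) (within 20%)
  resid_sd <- replicate(20, {
    noisy <- fx$x + rnorm(length(fx$x), 0, 0.2)
    e <- ensemble_average(noisy, fs, ann$r_times, "ecg")
    sd(e$beat - single)
  })
  expect_equal(mean(resid_sd), 0.2 / sqrt(ens$n_beats_averaged),
               tolerance = 0.2)

  # one wildly corrupted beat is dropped, leaving the ensemble unchanged
  corrupted <- fx$x
  ri5 <- round(ann$r_times[5] * fs)
  corrupted[(ri5 - 90):(ri5 + 290)] <- rnorm(381, 0, 5)
  e2 <- ensemble_average(corrupted, fs, ann$r_times, "ecg")
  expect_equal(e2$n_beats_averaged, ens$n_beats_averaged - 1L)
  expect_equal(e2$beat, ens$beat, tolerance = 1e-6)

  expect_error(ensemble_average(fx$x, fs, ann$r_times[1:3]), "at least 5")
})

test_that("S1/S2 segmentation recovers planted burst timings", {
  ens <- make_pcg_beat(s1 = 0.04, s2 = 0.30)
  hs <- extract_s1_s2(ens)
  expect_lte(abs(hs$s1_time - 0.04) * ens$fs, 1)
  expect_lte(abs(hs$s2_time - 0.30) * ens$fs, 1)
  expect_equal(hs$s1s2_rms_ratio, 1.0 / 0.7, tolerance = 0.05)

  # S2 removed: its features go missing, S1 survives
  ens0 <- make_pcg_beat(a2 = 0)
  hs0 <- extract_s1_s2(ens0)
  expect_true(is.na(hs0$s2_time))
  expect_false(is.na(hs0$s1_time))

  # amplitude scaling: RMS homogeneous of degree 1, ratio invariant
  ens2 <- make_pcg_beat()
  ens2$beat <- 2 * ens2$beat
  hs2 <- extract_s1_s2(ens2)
  expect_equal(hs2$s1_rms, 2 * hs$s1_rms, tolerance = 1e-10)
  expect_equal(hs2$s2_rms, 2 * hs$s2_rms, tolerance = 1e-10)
  expect_equal(hs2$s1s2_rms_ratio, hs$s1s2_rms_ratio, tolerance = 1e-10)
})

test_that("band RMS features isolate the configured bands", {
  cfg <- default_config()
  fs <- 500
  t <- (0:(2 * fs - 1)) / fs
  a <- 0.3
  tone <- a * sqrt(2) * sin(2 * pi * 75 * t)      # RMS exactly a
  bf <- band_features(tone, fs, cfg)
  expect_equal(unname(bf["s_mid"]), a, tolerance = 0.02)
  expect_lt(bf["s_low"], 0.05 * a)
  expect_lt(bf["s_high"], 0.05 * a)

  expect_equal(unname(band_features(numeric(fs), fs, cfg)),
               rep(0, 4))

  bad <- cfg; bad$features$band_high_hz <- c(100, 260)
  expect_error(validate_config(bad), "Nyquist")
  expect_error(band_features(tone, fs, bad), "Nyquist")
})

test_that("impedance features recover planted respiration parameters", {
  cfg <- default_config()
  fs <- 50
  t <- (0:(60 * fs - 1)) / fs
  z0 <- 25; A <- 0.5
  x1 <- z0 + A * sin(2 * pi * (15 / 60) * t)
  x2 <- z0 + 0.3 * sin(2 * pi * (15 / 60) * t + 1)
  f <- impedance_features(x1, x2, fs, cfg)
  expect_lt(abs(f$respiration_rate_1 - 15), 0.5)
  expect_lt(abs(f$respiration_rate_2 - 15), 0.5)
  expect_equal(f$relative_tidal_volume_1, 2 * A / z0, tolerance = 0.05)
  expect_equal(f$mean_impedance, z0, tolerance = 1e-6)

  g <- impedance_features(rep(z0, 60 * fs), x2, fs, cfg)
  expect_true(is.na(g$respiration_rate_1))
  expect_equal(g$relative_tidal_volume_1, 0)
})

test_that("QRS duration is read off the ensemble at the 10% threshold", {
  fx <- make_ecg(hr = 60, dur = 62, qrs = 0.10)
  ann <- detect_r_peaks(fx$x, fx$fs)
  ens <- ensemble_average(fx$x, fx$fs, ann$r_times, "ecg")
  expect_equal(qrs_duration_from_ensemble(ens), 0.10, tolerance = 2 / fx$fs)
})

test_that("feature vectors are complete on clean data and flag missing parts", {
  fx <- noise_free_session()
  mask <- assess_quality(fx$ses$recording, fx$cfg)
  w <- associate_window(mask, fx$ses$observations$timestamp_s[4], fx$cfg)
  slices <- window_slices(fx$ses$recording, w)
  fv <- build_feature_vector(slices, fx$subject, fx$cfg)
  expect_true(is.data.frame(fv))
  expect_true(all(feature_registry() %in% names(fv)))
  expect_false(any(unlist(fv[paste0("missing_", feature_registry())])))

  # identical windows give identical vectors
  fv2 <- build_feature_vector(slices, fx$subject, fx$cfg)
  expect_identical(fv, fv2)

  # PCG zeroed: heart-sound features flagged, ECG/impedance intact
  slices0 <- slices
  slices0$pcg$samples <- numeric(length(slices0$pcg$samples))
  fv0 <- build_feature_vector(slices0, fx$subject, fx$cfg)
  expect_true(is.data.frame(fv0))
  expect_true(fv0$missing_r_to_s2)
  expect_false(fv0$missing_mean_ibi)
  expect_false(fv0$missing_respiration_rate_1)
  expect_equal(fv0$mean_ibi, fv$mean_ibi)

  # everything signal-borne unusable: observation dropped with a reason
  for (nm in c("ecg1", "ecg2", "pcg")) {
    slices0[[nm]]$samples <- numeric(length(slices0[[nm]]$samples))
  }
  slices0$imp1$samples <- rep(25, length(slices0$imp1$samples))
  slices0$imp2$samples <- rep(25, length(slices0$imp2$samples))
  dropped <- build_feature_vector(slices0, fx$subject, fx$cfg)
  expect_false(is.data.frame(dropped))
  expect_match(attr(dropped, "reason"), "missing_fraction")
})

test_that("timing features are invariant to signal amplitude scaling", {
  fx <- noise_free_session()
  mask <- assess_quality(fx$ses$recording, fx$cfg)
  w <- associate_window(mask, fx$ses$observations$timestamp_s[6], fx$cfg)
  slices <- window_slices(fx$ses$recording, w)
  fv <- build_feature_vector(slices, fx$subject, fx$cfg)
  scaled <- slices
  scaled$ecg1$samples <- 3 * scaled$ecg1$samples
  scaled$pcg$samples <- 3 * scaled$pcg$samples
  fv3 <- build_feature_vector(scaled, fx$subject, fx$cfg)
  for (nm in c("r_to_s1", "r_to_s2", "mean_ibi", "qrs_duration",
               "s1s2_rms_ratio")) {
    expect_equal(fv3[[nm]], fv[[nm]], tolerance = 1e-8, label = nm)
  }
  expect_equal(fv3$s1_rms, 3 * fv$s1_rms, tolerance = 1e-8)
})
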