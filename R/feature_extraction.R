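# Per-window feature computation: ECG beat detection and ensemble
# averaging, S1/S2 heart-sound segmentation on the ensemble, spectral-band
# RMS features, impedance-pneumography respiration features, and assembly
# of the model feature vector.

#' Names of the model feature registry
#'
#' Signal features first, demographics last. Every feature vector carries
#' exactly these columns; missing values are flagged, never silent.
#' @return character vector.
#' @export
feature_registry <- function() {
  c("r_to_s1", "r_to_s2", "mean_ibi", "qrs_duration",
    "s1_rms", "s2_rms", "s1s2_rms_ratio",
    "s_low", "s_mid", "s_high", "s1_low",
    "respiration_rate_1", "respiration_rate_2",
    "relative_tidal_volume_1", "relative_tidal_volume_2", "mean_impedance",
    "age", "sex_male", "height", "weight")
}

#' @keywords internal
#' @noRd
demographic_features <- function() c("age", "sex_male", "height", "weight")

#' Detect ECG R-peak times
#'
#' Pan–Tompkins-style detector: band-pass 5–25 Hz, differentiate, square,
#' 150-ms moving-window integration, then chunk-local adaptive thresholding
#' with a 250-ms refractory period. Peak locations are refined to the raw
#' signal maximum near each detection. Chunk-local thresholds keep
#' detection working on clean stretches even when another part of the
#' record is swamped by movement noise.
#'
#' @param x ECG samples.
#' @param fs sampling rate, Hz.
#' @param screen drop RR intervals outside \[0.3, 2\] s (merging peaks that
#'   are implausibly close).
#' @return numeric vector of R times in seconds.
#' @export
detect_r_peak_times <- function(x, fs, screen = TRUE) {
  if (length(x) < 2 * fs) stop("need at least 2 s of ECG", call. = FALSE)
  if (stats::var(x) < 1e-12) stop("flat ECG signal: no beats", call. = FALSE)
  bp <- bandpass(x, fs, 5, 25, order = 3)
  d <- c(0, diff(bp)) * fs
  sq <- d^2
  integ <- moving_average(sq, round(0.15 * fs))
  refractory <- round(0.25 * fs)

  chunk_len <- as.integer(10 * fs)
  pad <- as.integer(fs)  # 1-s overlap so boundary beats are seen whole
  peaks <- integer(0)
  n <- length(integ)
  for (lo in seq(1L, n, by = chunk_len)) {
    hi <- min(n, lo + chunk_len - 1L)
    lo_p <- max(1L, lo - pad); hi_p <- min(n, hi + pad)
    seg <- integ[lo_p:hi_p]
    thr <- 0.3 * max(integ[lo:hi])
    if (thr <= 0) next
    p <- find_peaks(seg, min_height = thr, min_distance = refractory) + lo_p - 1L
    peaks <- c(peaks, p[p >= lo & p <= hi])
  }
  if (!length(peaks)) stop("no beats detected", call. = FALSE)
  # refine near the integrated peak on the zero-phase band-passed signal
  # (its R deflection stays centered and carries far less wideband noise
  # than the raw trace)
  r_idx <- vapply(peaks, function(p) {
    lo <- max(1, p - round(0.15 * fs))
    hi <- min(length(x), p + round(0.05 * fs))
    as.integer(lo + which.max(bp[lo:hi]) - 1)
  }, integer(1))
  r_idx <- sort(unique(r_idx))
  # re-apply refractory after refinement
  if (length(r_idx) > 1) {
    keep <- c(TRUE, diff(r_idx) > refractory)
    while (!all(keep)) {
      r_idx <- r_idx[keep]
      keep <- c(TRUE, diff(r_idx) > refractory)
    }
  }
  r <- (r_idx - 1) / fs
  if (screen && length(r) > 1) {
    rr <- diff(r)
    ok <- rr >= 0.3 & rr <= 2.0
    r <- r[c(TRUE, ok)]
  }
  r
}

#' Detect R peaks and annotate beats
#'
#' @param ecg ECG samples (at least 10 s).
#' @param fs sampling rate, Hz.
#' @return list of class `"beat_annotations"`: `r_times`, `rr_intervals`,
#'   `mean_interbeat_interval`. Fewer than 5 detected beats is an error
#'   (window rejection).
#' @export
detect_r_peaks <- function(ecg, fs) {
  if (length(ecg) < 10 * fs) stop("need at least 10 s of ECG", call. = FALSE)
  r <- detect_r_peak_times(ecg, fs, screen = TRUE)
  if (length(r) < 5) stop("fewer than 5 beats detected: window rejected",
                          call. = FALSE)
  rr <- diff(r)
  structure(list(r_times = r, rr_intervals = rr,
                 mean_interbeat_interval = mean(rr)),
            class = "beat_annotations")
}

#' Beat-aligned ensemble average
#'
#' Segments the signal around each R time (20% of the median RR before R,
#' the rest after), drops outlier beats whose correlation with the pointwise
#' mean falls below 0.5, and averages the survivors. Requires at least 5
#' surviving beats.
#'
#' @param x signal samples (ECG or PCG).
#' @param fs sampling rate, Hz.
#' @param r_times R-peak times in seconds (from the ECG).
#' @param mode `"ecg"` or `"pcg"` (recorded in the result).
#' @return list of class `"ensemble_beat"`: `beat` (averaged samples),
#'   `fs`, `r_index` (sample index of R within the beat), `median_rr`,
#'   `n_beats_averaged`.
#' @export
ensemble_average <- function(x, fs, r_times, mode = c("ecg", "pcg")) {
  mode <- match.arg(mode)
  if (length(r_times) < 5) stop("need at least 5 beats", call. = FALSE)
  med_rr <- stats::median(diff(r_times))
  pre <- round(0.2 * med_rr * fs)
  post <- round(med_rr * fs) - pre
  len <- pre + post
  r_idx <- round(r_times * fs) + 1L
  ok <- r_idx - pre >= 1L & r_idx + post - 1L <= length(x)
  r_idx <- r_idx[ok]
  if (length(r_idx) < 5) stop("fewer than 5 complete beats", call. = FALSE)
  beats <- vapply(r_idx, function(ri) x[(ri - pre):(ri + post - 1L)],
                  numeric(len))
  m <- rowMeans(beats)
  cors <- suppressWarnings(apply(beats, 2L, stats::cor, y = m))
  keep <- is.na(cors) | cors >= 0.5     # NA: zero-variance beat vs identical mean
  if (sum(keep) < 5) stop("fewer than 5 beats survive outlier screening",
                          call. = FALSE)
  structure(list(beat = rowMeans(beats[, keep, drop = FALSE]), fs = fs,
                 r_index = pre + 1L, median_rr = med_rr,
                 n_beats_averaged = sum(keep), mode = mode),
            class = "ensemble_beat")
}

#' S1/S2 segmentation of an ensemble-averaged heart-sound beat
#'
#' The amplitude envelope (Hilbert magnitude, lightly smoothed) is searched
#' for its strongest peak in (0, 0.25 RR\] after R (S1) and in
#' (0.25 RR, 0.6 RR\] (S2). A peak must rise above the noise floor
#' (3x the median envelope and 5% of its maximum) or the corresponding
#' features are flagged missing. RMS amplitudes are computed over a
#' +/-40 ms window around each detected peak on the raw ensemble.
#'
#' @param ens `"ensemble_beat"` of the PCG.
#' @return list of class `"heart_sound_features"`: `s1_time`, `s2_time`
#'   (seconds after R; `NA` when missing), `s1_rms`, `s2_rms`,
#'   `s1s2_rms_ratio`.
#' @export
extract_s1_s2 <- function(ens) {
  stopifnot(inherits(ens, "ensemble_beat"))
  fs <- ens$fs
  env <- moving_average(envelope_hilbert(ens$beat), round(0.005 * fs))
  if (max(env) <= .Machine$double.eps) {
    return(structure(list(s1_time = NA_real_, s2_time = NA_real_,
                          s1_rms = NA_real_, s2_rms = NA_real_,
                          s1s2_rms_ratio = NA_real_),
                     class = "heart_sound_features"))
  }
  floor_level <- max(3 * stats::median(env), 0.05 * max(env))
  rr <- ens$median_rr
  rel_t <- (seq_along(env) - ens$r_index) / fs

  search <- function(lo_s, hi_s) {
    idx <- which(rel_t > lo_s & rel_t <= hi_s)
    if (!length(idx)) return(NULL)
    p <- idx[which.max(env[idx])]
    if (env[p] < floor_level) return(NULL)
    refine_peak(env, p)
  }
  rms_at <- function(t_rel) {
    c0 <- ens$r_index + t_rel * fs
    lo <- max(1L, round(c0 - 0.04 * fs)); hi <- min(length(ens$beat), round(c0 + 0.04 * fs))
    sqrt(mean(ens$beat[lo:hi]^2))
  }

  p1 <- search(0, 0.25 * rr)
  p2 <- search(0.25 * rr, 0.6 * rr)
  s1_time <- if (is.null(p1)) NA_real_ else (p1 - ens$r_index) / fs
  s2_time <- if (is.null(p2)) NA_real_ else (p2 - ens$r_index) / fs
  s1_rms <- if (is.na(s1_time)) NA_real_ else rms_at(s1_time)
  s2_rms <- if (is.na(s2_time)) NA_real_ else rms_at(s2_time)
  structure(list(s1_time = s1_time, s2_time = s2_time,
                 s1_rms = s1_rms, s2_rms = s2_rms,
                 s1s2_rms_ratio = s1_rms / s2_rms),
            class = "heart_sound_features")
}

#' Spectral-band RMS features of a heart-sound segment
#'
#' RMS of the band-pass-filtered signal in the three configured bands
#' (defaults 20–50, 50–100, 100–240 Hz), plus `s1_low`: the low-band RMS
#' restricted to +/-40 ms around the S1 location when one is supplied.
#'
#' @param x PCG samples (ensemble beat or raw window).
#' @param fs sampling rate, Hz.
#' @param cfg pipeline config (uses `features`).
#' @param s1_center_s S1 location in seconds from the start of `x`, or
#'   `NA`/`NULL` to skip `s1_low`.
#' @return named numeric: `s_low`, `s_mid`, `s_high`, `s1_low`.
#' @export
band_features <- function(x, fs, cfg = default_config(), s1_center_s = NULL) {
  ft <- cfg$features
  if (stats::var(x) < 1e-30) {
    return(c(s_low = 0, s_mid = 0, s_high = 0, s1_low = 0))
  }
  rms <- function(v) sqrt(mean(v^2))
  low <- bandpass(x, fs, ft$band_low_hz[1], ft$band_low_hz[2], order = 4)
  mid <- bandpass(x, fs, ft$band_mid_hz[1], ft$band_mid_hz[2], order = 4)
  high <- bandpass(x, fs, ft$band_high_hz[1], ft$band_high_hz[2], order = 4)
  s1_low <- NA_real_
  if (!is.null(s1_center_s) && !is.na(s1_center_s)) {
    c0 <- round(s1_center_s * fs)
    lo <- max(1L, c0 - round(0.04 * fs)); hi <- min(length(x), c0 + round(0.04 * fs))
    s1_low <- rms(low[lo:hi])
  }
  c(s_low = rms(low), s_mid = rms(mid), s_high = rms(high), s1_low = s1_low)
}

#' Respiration features from the thoracic-impedance channels
#'
#' Per channel, the respiration rate is the dominant peak of the
#' zero-padded periodogram within the respiration band (default
#' 0.07–1 Hz), refined by parabolic interpolation; it is flagged missing
#' when no peak rises 3x above the median spectrum level. The relative
#' tidal volume is the mean peak-to-trough respiratory excursion (estimated
#' as `2*sqrt(2)` times the RMS of the respiration-band signal, exact for a
#' sinusoid) divided by the channel's mean impedance. `mean_impedance` is
#' the window mean of channel 1.
#'
#' @param imp1,imp2 impedance samples (60-s windows).
#' @param fs sampling rate, Hz.
#' @param cfg pipeline config.
#' @return list of class `"impedance_features"`: `respiration_rate_1`,
#'   `respiration_rate_2` (breaths/min, `NA` when missing),
#'   `relative_tidal_volume_1`, `relative_tidal_volume_2`,
#'   `mean_impedance`.
#' @export
impedance_features <- function(imp1, imp2, fs, cfg = default_config()) {
  band <- cfg$features$resp_band_hz

  one_channel <- function(x) {
    mu <- mean(x)
    xd <- x - mu
    if (stats::var(x) < 1e-12) {
      return(list(rate = NA_real_, rtv = 0))
    }
    # periodogram, zero-padded 8x for frequency resolution
    nfft <- 2^ceiling(log2(length(xd) * 8))
    X <- stats::fft(c(xd * signal::hanning(length(xd)), numeric(nfft - length(xd))))
    pw <- Mod(X[seq_len(nfft %/% 2)])^2
    freqs <- (seq_len(nfft %/% 2) - 1) * fs / nfft
    in_band <- which(freqs >= band[1] & freqs <= band[2])
    p <- in_band[which.max(pw[in_band])]
    rate <- NA_real_
    if (pw[p] >= 3 * stats::median(pw[in_band])) {
      rate <- 60 * (refine_peak(pw, p) - 1) * fs / nfft
    }
    # respiratory excursion: low-pass to the respiration band's upper edge
    bf <- signal::butter(2, band[2] / (fs / 2), type = "low")
    filt <- as.numeric(signal::filtfilt(bf, xd))
    trim <- seq.int(floor(length(filt) * 0.05) + 1L, ceiling(length(filt) * 0.95))
    excursion <- 2 * sqrt(2) * sqrt(mean(filt[trim]^2))
    list(rate = rate, rtv = excursion / mu)
  }

  c1 <- one_channel(imp1)
  c2 <- one_channel(imp2)
  structure(list(respiration_rate_1 = c1$rate, respiration_rate_2 = c2$rate,
                 relative_tidal_volume_1 = c1$rtv,
                 relative_tidal_volume_2 = c2$rtv,
                 mean_impedance = mean(imp1)),
            class = "impedance_features")
}

#' QRS duration from an ensemble-averaged ECG beat
#'
#' Width of the contiguous interval around R where |signal| exceeds 10% of
#' the R amplitude, with linearly interpolated threshold crossings for
#' sub-sample resolution.
#'
#' @param ens `"ensemble_beat"` of the ECG.
#' @return duration in seconds.
#' @export
qrs_duration_from_ensemble <- function(ens) {
  stopifnot(inherits(ens, "ensemble_beat"))
  beat <- ens$beat
  r <- ens$r_index
  amp <- abs(beat[r])
  thr <- 0.1 * amp
  a <- abs(beat)
  left <- r
  while (left > 1L && a[left - 1L] > thr) left <- left - 1L
  right <- r
  while (right < length(a) && a[right + 1L] > thr) right <- right + 1L
  # interpolate the crossing on each side
  tl <- if (left > 1L) (left - 1) - (a[left] - thr) / (a[left] - a[left - 1L]) else left - 1
  tr <- if (right < length(a)) (right - 1) + (a[right] - thr) / (a[right] - a[right + 1L]) else right - 1
  (tr - tl) / ens$fs
}

#' Build the per-observation feature vector
#'
#' Runs the full extraction chain on the channel slices of one accepted
#' analysis window and appends the subject demographics. Every registry
#' feature is either computed or flagged missing (`NA` value plus a `TRUE`
#' missing flag); if more than the configured fraction of signal features
#' is missing the observation is dropped.
#'
#' @param slices channel slices from [window_slices()].
#' @param subject cohort row (needs `age`, `sex`, `height`, `weight`).
#' @param cfg pipeline config.
#' @return one-row data frame with the registry columns plus
#'   `missing_<name>` flag columns, or a `"dropped_feature_vector"` sentinel
#'   (with attribute `"reason"`) when dropped.
#' @export
build_feature_vector <- function(slices, subject, cfg = default_config()) {
  vals <- stats::setNames(rep(NA_real_, length(feature_registry())),
                          feature_registry())
  try_na <- function(expr) tryCatch(expr, error = function(e) NULL)

  ecg <- slices$ecg1
  ann <- try_na(detect_r_peaks(ecg$samples, ecg$fs))
  if (!is.null(ann)) {
    vals["mean_ibi"] <- ann$mean_interbeat_interval
    ens_ecg <- try_na(ensemble_average(ecg$samples, ecg$fs, ann$r_times, "ecg"))
    if (!is.null(ens_ecg)) {
      vals["qrs_duration"] <- try_na(qrs_duration_from_ensemble(ens_ecg)) %||% NA_real_
    }
    pcg <- slices$pcg
    ens_pcg <- try_na(ensemble_average(pcg$samples, pcg$fs, ann$r_times, "pcg"))
    if (!is.null(ens_pcg)) {
      hs <- try_na(extract_s1_s2(ens_pcg))
      if (!is.null(hs)) {
        vals["r_to_s1"] <- hs$s1_time
        vals["r_to_s2"] <- hs$s2_time
        vals["s1_rms"] <- hs$s1_rms
        vals["s2_rms"] <- hs$s2_rms
        vals["s1s2_rms_ratio"] <- hs$s1s2_rms_ratio
        s1_center <- if (is.na(hs$s1_time)) NULL else
          (ens_pcg$r_index / ens_pcg$fs) + hs$s1_time
        bf <- try_na(band_features(ens_pcg$beat, ens_pcg$fs, cfg, s1_center))
        if (!is.null(bf)) vals[names(bf)] <- bf
      }
    }
  }
  imp <- try_na(impedance_features(slices$imp1$samples, slices$imp2$samples,
                                   slices$imp1$fs, cfg))
  if (!is.null(imp)) {
    for (nm in c("respiration_rate_1", "respiration_rate_2",
                 "relative_tidal_volume_1", "relative_tidal_volume_2",
                 "mean_impedance")) {
      vals[nm] <- imp[[nm]]
    }
  }

  vals[!is.finite(vals)] <- NA_real_   # a zero-RMS denominator yields Inf

  vals["age"] <- as.numeric(subject$age)
  vals["sex_male"] <- as.numeric(subject$sex == "male")
  vals["height"] <- as.numeric(subject$height)
  vals["weight"] <- as.numeric(subject$weight)

  signal_names <- setdiff(feature_registry(), demographic_features())
  frac_missing <- mean(is.na(vals[signal_names]))
  if (frac_missing > cfg$features$max_missing_fraction) {
    return(structure(NA, class = "dropped_feature_vector",
                     reason = sprintf("missing_fraction_%.2f", frac_missing)))
  }
  row <- as.data.frame(as.list(vals))
  flags <- as.data.frame(as.list(stats::setNames(is.na(vals),
                                                 paste0("missing_", names(vals)))))
  cbind(row, flags)
}
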