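# Synthetic cohorts, sessions and raw multichannel waveforms with known
# ground-truth hemodynamics, so that every downstream stage of the pipeline
# can be exercised and verified without access to clinical recordings.

#' Generate a stratified synthetic cohort
#'
#' Draws subjects with demographics (age, sex, height, weight), an entry
#' blood pressure consistent with their target JNC 7 class, and baseline
#' hemodynamics (heart rate, respiration rate, systolic time intervals,
#' impedance levels) that parameterize waveform synthesis.
#'
#' Class counts are `floor(fraction * n)` per class with the rounding
#' residual assigned to the largest-fraction class, so counts always sum to
#' `n_subjects` and are deterministic.
#'
#' @param n_subjects number of subjects (>= 4).
#' @param class_fractions named fractions over
#'   `c("normal","prehypertension","stage1","stage2")`; must sum to 1.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return data frame, one row per subject, with class `"cohort"`.
#' @export
generate_cohort <- function(n_subjects,
                            class_fractions = c(normal = 0.20,
                                                prehypertension = 0.37,
                                                stage1 = 0.26,
                                                stage2 = 0.18),
                            seed = 1L) {
  if (n_subjects < 4) stop("n_subjects must be >= 4", call. = FALSE)
  if (any(class_fractions < 0) || abs(sum(class_fractions) - 1) > 0.05) {
    stop("class_fractions must be non-negative and sum to 1", call. = FALSE)
  }
  lv <- bp_class_levels()
  class_fractions <- class_fractions[lv]
  if (anyNA(class_fractions)) {
    stop("class_fractions must be named with the four JNC 7 classes", call. = FALSE)
  }
  counts <- floor(class_fractions * n_subjects)
  counts[which.max(class_fractions)] <-
    counts[which.max(class_fractions)] + (n_subjects - sum(counts))

  set.seed(seed)
  rows <- vector("list", length(lv))
  # entry-BP sampling boxes chosen so classify_jnc7 reproduces the class
  bp_box <- list(
    normal          = c(100, 118, 62, 78),
    prehypertension = c(120, 138, 78, 88),
    stage1          = c(140, 158, 84, 98),
    stage2          = c(160, 185, 96, 112)
  )
  age_box <- list(
    normal          = c(18, 55),
    prehypertension = c(25, 70),
    stage1          = c(35, 80),
    stage2          = c(40, 83)
  )
  for (k in seq_along(lv)) {
    m <- counts[[k]]
    if (m == 0L) next
    box <- bp_box[[lv[k]]]
    sbp <- round_to_grid(stats::runif(m, box[1], box[2]))
    dbp <- round_to_grid(stats::runif(m, box[3], box[4]))
    sbp <- pmax(sbp, box[1]); sbp <- pmin(sbp, box[2] + 1)
    dbp <- pmax(dbp, box[3]); dbp <- pmin(dbp, pmin(box[4] + 1, sbp - 16))
    rows[[k]] <- data.frame(
      bp_class = lv[k],
      entry_sbp = sbp,
      entry_dbp = dbp,
      age = as.integer(round(stats::runif(m, age_box[[lv[k]]][1], age_box[[lv[k]]][2])))
    )
  }
  cohort <- do.call(rbind, rows)
  n <- nrow(cohort)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  if (n >= 2 && length(unique(sex)) == 1L) sex[1] <- setdiff(c("male", "female"), sex[1])
  cohort$sex <- sex
  cohort$height <- round(ifelse(sex == "male",
                                stats::rnorm(n, 176, 7), stats::rnorm(n, 163, 6)), 1)
  bmi <- pmax(17, stats::rnorm(n, 27, 4))
  cohort$weight <- round(bmi * (cohort$height / 100)^2, 1)

  # baseline hemodynamics (waveform-synthesis ground truth)
  cohort$heart_rate <- round(stats::runif(n, 58, 90), 1)
  cohort$respiration_rate <- round(stats::runif(n, 10, 18), 1)
  cohort$r_to_s1 <- round(pmax(0.02, stats::rnorm(n, 0.04, 0.005)), 4)
  cohort$qrs_duration <- round(stats::runif(n, 0.08, 0.11), 4)
  cohort$baseline_impedance <- round(stats::runif(n, 22, 30), 2)
  cohort$tidal_amplitude <- round(stats::runif(n, 0.3, 0.7), 3)
  cohort$tidal_amplitude_2 <- round(cohort$tidal_amplitude * stats::runif(n, 0.7, 1.3), 3)

  cohort$subject_id <- sprintf("S%03d", seq_len(n))
  cohort$bp_class <- factor(cohort$bp_class, levels = lv)
  rownames(cohort) <- NULL
  # invariant: entry class must agree with the sampled entry BP
  stopifnot(all(classify_jnc7(cohort$entry_sbp, cohort$entry_dbp) == cohort$bp_class))
  class(cohort) <- c("cohort", "data.frame")
  cohort[, c("subject_id", "age", "sex", "height", "weight",
             "entry_sbp", "entry_dbp", "bp_class",
             "heart_rate", "respiration_rate", "r_to_s1", "qrs_duration",
             "baseline_impedance", "tidal_amplitude", "tidal_amplitude_2")]
}

#' Conditions of the BP-modulation protocol
#' @return character vector of the four condition labels.
#' @export
protocol_conditions <- function() c("static", "warm_rest", "cold_walk", "rest")

#' Simulate true blood pressure under a protocol condition
#'
#' Applies the configured condition offset to the subject's entry BP plus a
#' subject-by-condition response term and reading-to-reading noise. Warm
#' stimulus lowers BP, cold pressor with walking raises it, so the expected
#' ordering is SBP(warm_rest) < SBP(static) < SBP(cold_walk). The pulse
#' pressure is floored at 15 mmHg.
#'
#' @param subject one-row data frame with `entry_sbp`, `entry_dbp` (a cohort
#'   row), or a named vector with those elements.
#' @param condition one of [protocol_conditions()].
#' @param n number of draws.
#' @param cfg pipeline config (uses `bp_modulation`).
#' @param subject_effect optional fixed subject-by-condition offsets
#'   `c(sbp=, dbp=)`; drawn from `N(0, subject_sd)` when `NULL`.
#' @return data frame with columns `sbp`, `dbp` (mmHg).
#' @export
simulate_condition_bp <- function(subject, condition, n = 1L,
                                  cfg = default_config(), subject_effect = NULL) {
  if (!condition %in% protocol_conditions()) {
    stop("unknown condition '", condition, "'", call. = FALSE)
  }
  mod <- cfg$bp_modulation
  if (is.null(subject_effect)) {
    subject_effect <- c(sbp = stats::rnorm(1, 0, mod$subject_sd),
                        dbp = stats::rnorm(1, 0, mod$subject_sd))
  }
  sbp <- as.numeric(subject[["entry_sbp"]]) + mod$sbp_offset[[condition]] +
    subject_effect[["sbp"]] + stats::rnorm(n, 0, mod$observation_sd)
  dbp <- as.numeric(subject[["entry_dbp"]]) + mod$dbp_offset[[condition]] +
    subject_effect[["dbp"]] + stats::rnorm(n, 0, mod$observation_sd)
  dbp <- pmin(dbp, sbp - 15)
  data.frame(sbp = sbp, dbp = dbp)
}

#' Session measurement schedule
#'
#' One block per condition, in protocol order; each block has a lead-in
#' followed by `obs_per_condition` consecutive scheduled readings spaced
#' `obs_spacing_s` apart (the protocol requires at least 60 s between
#' consecutive readings).
#'
#' @param cfg pipeline config (uses `protocol`).
#' @return data frame: `condition`, `block_start_s`, `timestamp_s`, one row
#'   per scheduled observation.
#' @export
session_schedule <- function(cfg = default_config()) {
  p <- cfg$protocol
  stopifnot(p$obs_spacing_s >= 60)
  block_dur <- p$lead_in_s + p$obs_per_condition * p$obs_spacing_s
  out <- list()
  t0 <- 0
  for (cond in p$conditions) {
    ts <- t0 + p$lead_in_s + (seq_len(p$obs_per_condition) - 1) * p$obs_spacing_s
    out[[cond]] <- data.frame(condition = cond, block_start_s = t0, timestamp_s = ts)
    t0 <- t0 + block_dur
  }
  sched <- do.call(rbind, out)
  rownames(sched) <- NULL
  attr(sched, "session_duration_s") <- t0
  sched
}

#' Hemodynamic ground truth for each scheduled observation
#'
#' Draws the per-observation true BP (via [simulate_condition_bp()] with one
#' subject-by-condition effect per block) and derives the waveform
#' parameters. When signal-BP coupling is enabled the R-to-S2 interval is an
#' affine, monotone-decreasing function of true SBP and the S1/S2 RMS ratio
#' an affine function of true DBP (plus jitter); with coupling disabled both
#' are drawn around fixed values so signal features carry no BP information
#' (the null configuration).
#'
#' @param subject cohort row.
#' @param sched schedule from [session_schedule()].
#' @param cfg pipeline config.
#' @return data frame, one row per observation, with true BP and all
#'   waveform parameters.
#' @export
observation_ground_truth <- function(subject, sched, cfg = default_config()) {
  cp <- cfg$coupling
  n <- nrow(sched)
  gt <- sched
  gt$true_sbp <- NA_real_; gt$true_dbp <- NA_real_
  for (cond in unique(sched$condition)) {
    idx <- which(sched$condition == cond)
    eff <- c(sbp = stats::rnorm(1, 0, cfg$bp_modulation$subject_sd),
             dbp = stats::rnorm(1, 0, cfg$bp_modulation$subject_sd))
    bp <- simulate_condition_bp(subject, cond, n = length(idx), cfg = cfg,
                                subject_effect = eff)
    gt$true_sbp[idx] <- bp$sbp
    gt$true_dbp[idx] <- bp$dbp
  }
  coupled <- isTRUE(cp$enabled)
  # condition responses of HR and respiration are themselves a signal-BP
  # pathway (condition drives both), so the null configuration zeroes them
  hr_off <- if (coupled) c(static = 0, warm_rest = -5, cold_walk = 15, rest = 0)
            else c(static = 0, warm_rest = 0, cold_walk = 0, rest = 0)
  rr_off <- if (coupled) c(static = 0, warm_rest = -1, cold_walk = 4, rest = 0)
            else hr_off * 0
  gt$heart_rate <- subject$heart_rate + hr_off[gt$condition] + stats::rnorm(n, 0, 1)
  gt$respiration_rate <- pmax(6, subject$respiration_rate + rr_off[gt$condition] +
                                stats::rnorm(n, 0, 0.5))
  sbp_for_signal <- if (coupled) gt$true_sbp else rep(120, n)
  dbp_for_signal <- if (coupled) gt$true_dbp else rep(80, n)
  gt$r_to_s2 <- cp$r_to_s2_intercept_s + cp$r_to_s2_slope_s_per_mmhg * sbp_for_signal +
    stats::rnorm(n, 0, cp$r_to_s2_jitter_sd_s)
  gt$r_to_s1 <- subject$r_to_s1 + stats::rnorm(n, 0, 0.001)
  gt$s1s2_rms_ratio <- pmax(0.5, cp$s1s2_ratio_intercept +
    cp$s1s2_ratio_slope_per_mmhg * (dbp_for_signal - 80) +
    stats::rnorm(n, 0, cp$s1s2_ratio_jitter_sd))
  if (coupled) {
    gt$respiration_rate <- pmax(6, gt$respiration_rate +
      cp$resp_rate_slope_per_mmhg * (gt$true_sbp - 120))
  }
  gt$qrs_duration <- subject$qrs_duration
  gt$baseline_impedance <- subject$baseline_impedance
  gt$tidal_amplitude <- subject$tidal_amplitude
  gt$tidal_amplitude_2 <- subject$tidal_amplitude_2
  # keep valve timings physiological and inside the cardiac cycle
  gt$r_to_s2 <- pmin(pmax(gt$r_to_s2, gt$r_to_s1 + 0.08), 60 / gt$heart_rate * 0.55)
  gt$obs_id <- sprintf("%s_O%02d", subject$subject_id, seq_len(n))
  gt
}

#' Simulate dual-observer (and wrist-cuff) readings of a true BP
#'
#' Each observer reads the true pressure plus independent Gaussian noise,
#' recorded to the nearest 2 mmHg (ties round to even). The optional wrist
#' cuff reads with a larger bias and noise, emulating a consumer device
#' measured sequentially after the reference.
#'
#' @param true_sbp,true_dbp true pressures, mmHg (vectorized).
#' @param cfg pipeline config (uses `observers`).
#' @param cuff include wrist-cuff columns.
#' @return data frame: `obs1_sbp`, `obs1_dbp`, `obs2_sbp`, `obs2_dbp` and,
#'   when `cuff`, `cuff_sbp`, `cuff_dbp`.
#' @export
simulate_observers <- function(true_sbp, true_dbp, cfg = default_config(),
                               cuff = TRUE) {
  stopifnot(all(true_sbp > 0), all(true_dbp > 0))
  ob <- cfg$observers
  n <- length(true_sbp)
  read2 <- function(x) round_to_grid(x + stats::rnorm(n, 0, ob$noise_sd_mmhg), 2)
  out <- data.frame(
    obs1_sbp = read2(true_sbp), obs1_dbp = read2(true_dbp),
    obs2_sbp = read2(true_sbp), obs2_dbp = read2(true_dbp)
  )
  if (cuff) {
    out$cuff_sbp <- round(true_sbp + ob$cuff_bias_mmhg +
                            stats::rnorm(n, 0, ob$cuff_noise_sd_mmhg))
    out$cuff_dbp <- round(true_dbp + ob$cuff_bias_mmhg +
                            stats::rnorm(n, 0, ob$cuff_noise_sd_mmhg))
  }
  out
}

#' Synthesize a full session recording for one subject
#'
#' Builds the six-channel recording (`ecg1`, `ecg2`, `pcg`, `imp1`, `imp2`,
#' `activity`) over the whole session, with hemodynamics piecewise constant
#' between scheduled observations (so the 60-s analysis window preceding an
#' observation sees that observation's ground truth). Waveform models:
#'
#' * ECG: per beat, a sum of Gaussians — P wave, an R wave whose width is
#'   set so the interval where |signal| exceeds 10% of the R amplitude
#'   equals the planted QRS duration, and a T wave — placed at RR intervals
#'   with configurable heart-rate variability.
#' * PCG: Gaussian-windowed tone bursts centered `r_to_s1` (low-frequency
#'   dominant S1) and `r_to_s2` (S2) after each R peak; burst amplitudes
#'   carry the planted S1/S2 RMS ratio.
#' * Impedance: baseline + tidal sinusoid at the respiration rate (phase-
#'   continuous across segments) + a small cardiac ripple; channel 2 has an
#'   independent tidal amplitude.
#' * Activity: near-zero baseline; injected movement epochs drive the
#'   channel high and corrupt all channels with large-amplitude noise.
#'
#' @param subject cohort row.
#' @param cfg pipeline config.
#' @param seed integer seed.
#' @param sched optional schedule (defaults to [session_schedule()]).
#' @return list: `recording` (a [new_recording()] object), `observations`
#'   (schedule + observer/cuff readings), `ground_truth` (planted
#'   parameters per observation), `movement_epochs` (data frame of injected
#'   bad epochs).
#' @export
synthesize_recording <- function(subject, cfg = default_config(), seed = 1L,
                                 sched = NULL) {
  set.seed(seed)
  if (is.null(sched)) sched <- session_schedule(cfg)
  dur <- attr(sched, "session_duration_s") %||%
    (max(sched$timestamp_s) + cfg$protocol$obs_spacing_s)
  gt <- observation_ground_truth(subject, sched, cfg)
  sg <- cfg$signals
  fs_ecg <- sg$fs[["ecg"]]; fs_pcg <- sg$fs[["pcg"]]
  fs_imp <- sg$fs[["imp"]]; fs_act <- sg$fs[["activity"]]

  # piecewise-constant parameter lookup: observation i governs (t_{i-1}, t_i]
  seg_of <- function(t) pmin(findInterval(t, gt$timestamp_s, left.open = TRUE) + 1L,
                             nrow(gt))

  ## --- beat train over the whole session ---------------------------------
  r_times <- numeric(0)
  t <- 0.3
  while (t < dur) {
    r_times <- c(r_times, t)
    seg <- seg_of(t)
    rr <- 60 / gt$heart_rate[seg]
    if (sg$hrv_sd_s > 0) rr <- rr + stats::rnorm(1, 0, sg$hrv_sd_s)
    t <- t + max(0.3, rr)
  }
  beat_seg <- seg_of(r_times)

  ## --- ECG ----------------------------------------------------------------
  # events are accumulated as (index, value) chunks and summed in one pass
  # (rowsum) to avoid copying megasample vectors per beat
  render_events <- function(n, fs, centers, amps, sds, freqs = NULL) {
    idx_chunks <- vector("list", length(centers))
    val_chunks <- vector("list", length(centers))
    for (i in seq_along(centers)) {
      lo <- max(1L, floor((centers[i] - 4 * sds[i]) * fs) + 1L)
      hi <- min(n, ceiling((centers[i] + 4 * sds[i]) * fs) + 1L)
      if (lo > hi) next
      tt <- (seq.int(lo, hi) - 1) / fs - centers[i]
      v <- amps[i] * exp(-0.5 * (tt / sds[i])^2)
      if (!is.null(freqs)) v <- v * cos(2 * pi * freqs[i] * tt)
      idx_chunks[[i]] <- seq.int(lo, hi)
      val_chunks[[i]] <- v
    }
    idx <- unlist(idx_chunks, use.names = FALSE)
    out <- numeric(n)
    if (length(idx)) {
      agg <- rowsum(unlist(val_chunks, use.names = FALSE), idx)
      out[as.integer(rownames(agg))] <- agg[, 1]
    }
    out
  }
  n_ecg <- round(dur * fs_ecg)
  # R-wave sigma such that |x| > 0.1 * amplitude spans exactly qrs_duration
  qrs_sigma <- gt$qrs_duration[beat_seg] / (2 * sqrt(2 * log(10)))
  nb <- length(r_times)
  ecg <- render_events(
    n_ecg, fs_ecg,
    centers = c(r_times - 0.16, r_times, r_times + 0.25),
    amps = rep(c(0.15, 1.0, 0.30), each = nb),
    sds = c(rep(0.02, nb), qrs_sigma, rep(0.05, nb))
  )
  ecg1 <- ecg
  ecg2 <- 0.8 * ecg
  if (sg$ecg_noise_sd > 0) {
    ecg1 <- ecg1 + stats::rnorm(n_ecg, 0, sg$ecg_noise_sd)
    ecg2 <- ecg2 + stats::rnorm(n_ecg, 0, sg$ecg_noise_sd)
  }

  ## --- PCG ----------------------------------------------------------------
  n_pcg <- round(dur * fs_pcg)
  burst_sd <- 0.010
  s1_amp <- 1.0
  pcg <- render_events(
    n_pcg, fs_pcg,
    centers = c(r_times + gt$r_to_s1[beat_seg], r_times + gt$r_to_s2[beat_seg]),
    amps = c(rep(s1_amp, nb), s1_amp / gt$s1s2_rms_ratio[beat_seg]),
    sds = rep(burst_sd, 2 * nb),
    freqs = rep(c(35, 55), each = nb)
  )
  if (sg$pcg_noise_sd > 0) pcg <- pcg + stats::rnorm(n_pcg, 0, sg$pcg_noise_sd)

  ## --- impedance (phase-continuous tidal sinusoid) ------------------------
  n_imp <- round(dur * fs_imp)
  t_imp <- (seq_len(n_imp) - 1) / fs_imp
  seg_imp <- seg_of(t_imp)
  f_resp <- gt$respiration_rate[seg_imp] / 60
  phase <- 2 * pi * cumsum(f_resp) / fs_imp
  ripple <- sg$cardiac_ripple_ohm *
    sin(2 * pi * cumsum(gt$heart_rate[seg_imp] / 60) / fs_imp)
  imp1 <- gt$baseline_impedance[seg_imp] + gt$tidal_amplitude[seg_imp] * sin(phase) + ripple
  imp2 <- gt$baseline_impedance[seg_imp] * 0.9 +
    gt$tidal_amplitude_2[seg_imp] * sin(phase + 0.3) + ripple
  if (sg$imp_noise_sd > 0) {
    imp1 <- imp1 + stats::rnorm(n_imp, 0, sg$imp_noise_sd)
    imp2 <- imp2 + stats::rnorm(n_imp, 0, sg$imp_noise_sd)
  }

  ## --- activity + movement epochs -----------------------------------------
  n_act <- round(dur * fs_act)
  activity <- abs(stats::rnorm(n_act, 0, 0.02))
  epochs <- data.frame(start_s = numeric(0), end_s = numeric(0))
  n_ep <- sg$movement_epochs_per_session
  if (n_ep > 0) {
    starts <- sort(stats::runif(n_ep, 0, max(1, dur - sg$movement_duration_s)))
    epochs <- data.frame(start_s = starts, end_s = starts + sg$movement_duration_s)
    corrupt <- function(x, fs) {
      for (j in seq_len(nrow(epochs))) {
        lo <- max(1L, floor(epochs$start_s[j] * fs) + 1L)
        hi <- min(length(x), ceiling(epochs$end_s[j] * fs))
        x[lo:hi] <- x[lo:hi] + stats::rnorm(hi - lo + 1, 0, sg$movement_amplitude)
      }
      x
    }
    ecg1 <- corrupt(ecg1, fs_ecg); ecg2 <- corrupt(ecg2, fs_ecg)
    pcg <- corrupt(pcg, fs_pcg)
    imp1 <- corrupt(imp1, fs_imp); imp2 <- corrupt(imp2, fs_imp)
    for (j in seq_len(nrow(epochs))) {
      lo <- max(1L, floor(epochs$start_s[j] * fs_act) + 1L)
      hi <- min(n_act, ceiling(epochs$end_s[j] * fs_act))
      activity[lo:hi] <- activity[lo:hi] + sg$movement_amplitude
    }
  }

  rec <- new_recording(
    channels = list(
      ecg1 = list(samples = ecg1, fs = fs_ecg, units = "mV"),
      ecg2 = list(samples = ecg2, fs = fs_ecg, units = "mV"),
      pcg = list(samples = pcg, fs = fs_pcg, units = "a.u."),
      imp1 = list(samples = imp1, fs = fs_imp, units = "ohm"),
      imp2 = list(samples = imp2, fs = fs_imp, units = "ohm"),
      activity = list(samples = activity, fs = fs_act, units = "g")
    ),
    subject_id = subject$subject_id,
    start_time = 0
  )

  obs <- cbind(
    data.frame(subject_id = subject$subject_id, obs_id = gt$obs_id,
               timestamp_s = gt$timestamp_s, condition = gt$condition),
    simulate_observers(gt$true_sbp, gt$true_dbp, cfg)
  )
  obs$cuff_timestamp_s <- obs$timestamp_s + cfg$observers$cuff_delay_s

  # planted mean interbeat interval actually realized per observation window
  gt$mean_ibi <- 60 / gt$heart_rate
  list(recording = rec, observations = obs, ground_truth = gt,
       movement_epochs = epochs, r_times = r_times)
}

#' Fast feature-level simulation of a study dataset
#'
#' Draws the per-observation feature vectors directly from the same
#' ground-truth hemodynamics that drive waveform synthesis, bypassing
#' waveform rendering and signal processing. The feature values equal the
#' planted parameters plus small measurement noise — the noise-free
#' waveform path is verified elsewhere to recover the planted parameters to
#' within a sample, so this path is statistically equivalent for
#' model-level experiments and orders of magnitude faster. Used for the
#' Monte-Carlo model-superiority and null studies.
#'
#' @param cfg pipeline config (cohort size, protocol, coupling all honored).
#' @param seed integer seed.
#' @return data frame: one row per reconciled observation, with the full
#'   feature registry, demographics, `sbp`/`dbp` reference targets,
#'   `subject_id`, `condition`, `obs_id`.
#' @export
simulate_feature_dataset <- function(cfg = default_config(), seed = 1L) {
  set.seed(seed)
  cohort <- generate_cohort(cfg$cohort$n_subjects, cfg$cohort$class_fractions,
                            seed = derive_seed(seed, 17L))
  sched <- session_schedule(cfg)
  set.seed(derive_seed(seed, 29L))
  out <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    subject <- cohort[i, ]
    gt <- observation_ground_truth(subject, sched, cfg)
    n <- nrow(gt)
    ob <- simulate_observers(gt$true_sbp, gt$true_dbp, cfg)
    sbp_ref <- reconcile_observers(ob$obs1_sbp, ob$obs2_sbp)
    dbp_ref <- reconcile_observers(ob$obs1_dbp, ob$obs2_dbp)
    s1_rms <- exp(stats::rnorm(n, 0, 0.15))           # gain varies per window
    s2_rms <- s1_rms / gt$s1s2_rms_ratio
    f <- data.frame(
      obs_id = gt$obs_id, subject_id = subject$subject_id,
      condition = gt$condition, timestamp_s = gt$timestamp_s,
      r_to_s1 = gt$r_to_s1 + stats::rnorm(n, 0, 0.001),
      r_to_s2 = gt$r_to_s2 + stats::rnorm(n, 0, 0.002),
      mean_ibi = 60 / gt$heart_rate + stats::rnorm(n, 0, 0.005),
      qrs_duration = gt$qrs_duration + stats::rnorm(n, 0, 0.002),
      s1_rms = s1_rms,
      s2_rms = s2_rms,
      s1s2_rms_ratio = s1_rms / s2_rms,
      s_low = 0.6 * s1_rms * exp(stats::rnorm(n, 0, 0.2)),
      s_mid = 0.4 * s2_rms * exp(stats::rnorm(n, 0, 0.2)),
      s_high = 0.1 * exp(stats::rnorm(n, 0, 0.2)),
      s1_low = 0.5 * s1_rms * exp(stats::rnorm(n, 0, 0.2)),
      respiration_rate_1 = gt$respiration_rate + stats::rnorm(n, 0, 0.3),
      respiration_rate_2 = gt$respiration_rate + stats::rnorm(n, 0, 0.3),
      relative_tidal_volume_1 = 2 * gt$tidal_amplitude / gt$baseline_impedance *
        exp(stats::rnorm(n, 0, 0.05)),
      relative_tidal_volume_2 = 2 * gt$tidal_amplitude_2 / (0.9 * gt$baseline_impedance) *
        exp(stats::rnorm(n, 0, 0.05)),
      mean_impedance = gt$baseline_impedance + stats::rnorm(n, 0, 0.1),
      age = subject$age, sex = subject$sex,
      sex_male = as.numeric(subject$sex == "male"),
      height = subject$height, weight = subject$weight,
      sbp = sbp_ref, dbp = dbp_ref,
      true_sbp = gt$true_sbp, true_dbp = gt$true_dbp
    )
    out[[i]] <- f
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[!is.na(res$sbp) & !is.na(res$dbp), ]
}
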