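#' Default pipeline configuration
#'
#' Returns the full nested list of parameters driving every stage of the
#' pipeline: cohort generation, the BP-modulation protocol, waveform
#' synthesis, quality screening, window association, feature bands, the
#' train/test split, feature selection, model hyperparameters and the
#' bootstrap sizes. All values are plain numbers/strings so the
#' configuration can round-trip through YAML or JSON.
#'
#' Defaults mirror the study conditions the generator emulates: a cohort
#' stratified 20/37/26/18% across the four JNC 7 classes, three consecutive
#' reference readings after each BP-modulating activity with at least 60 s
#' between readings, observers reading to the nearest 2 mmHg, an 80/20
#' observation-level split, a 2% impurity-importance selection threshold,
#' 10,000 paired bootstrap resamples for the model comparison and 1,000 for
#' the MAD confidence interval.
#'
#' @param n_subjects cohort size for the simulate stage (study size 120;
#'   the shipped demo config uses 40 to keep a full run short).
#' @return nested named list.
#' @export
default_config <- function(n_subjects = 120) {
  list(
    seed = 20260101L,
    cohort = list(
      n_subjects = as.integer(n_subjects),
      class_fractions = c(normal = 0.20, prehypertension = 0.37,
                          stage1 = 0.26, stage2 = 0.18)
    ),
    protocol = list(
      conditions = c("static", "warm_rest", "cold_walk", "rest"),
      lead_in_s = 90,           # settle time before the first reading of a block
      obs_spacing_s = 90,       # >= 60 s between consecutive readings
      obs_per_condition = 3L    # three consecutive readings per activity
    ),
    bp_modulation = list(
      # mean SBP/DBP offsets (mmHg) relative to entry BP, per condition
      sbp_offset = c(static = 0, warm_rest = -10, cold_walk = 15, rest = -4),
      dbp_offset = c(static = 0, warm_rest = -6, cold_walk = 10, rest = -3),
      subject_sd = 3,           # subject-by-condition response variability
      observation_sd = 3        # reading-to-reading variability
    ),
    signals = list(
      fs = c(ecg = 500, pcg = 500, imp = 50, activity = 25),
      hrv_sd_s = 0.01,
      ecg_noise_sd = 0.0,
      pcg_noise_sd = 0.0,
      imp_noise_sd = 0.0,
      cardiac_ripple_ohm = 0.02,
      movement_epochs_per_session = 1L,
      movement_duration_s = 20,
      movement_amplitude = 3
    ),
    coupling = list(
      enabled = TRUE,
      # R-to-S2 interval shortens with SBP (systolic time-interval surrogate)
      r_to_s2_intercept_s = 0.40,
      r_to_s2_slope_s_per_mmhg = -0.001,
      r_to_s2_jitter_sd_s = 0.002,
      # S1/S2 RMS ratio rises with DBP
      s1s2_ratio_intercept = 1.5,
      s1s2_ratio_slope_per_mmhg = 0.01,
      s1s2_ratio_jitter_sd = 0.02,
      # respiration rate drifts weakly with SBP
      resp_rate_slope_per_mmhg = 0.02
    ),
    observers = list(
      noise_sd_mmhg = 2,
      cuff_bias_mmhg = 3,
      cuff_noise_sd_mmhg = 5,
      cuff_delay_s = 60
    ),
    quality = list(
      # per-channel amplitude rails, in channel units
      saturation_rail = c(ecg1 = 5, ecg2 = 5, pcg = 5, imp1 = 60, imp2 = 60),
      saturation_run = 50L,
      variance_floor = 1e-10,
      movement_threshold = 0.5,
      rr_range_s = c(0.3, 2.0)
    ),
    window = list(
      mode = "preceding",       # "preceding" or "centered"
      lookback_s = 300,
      window_s = 60
    ),
    features = list(
      band_low_hz = c(20, 50),
      band_mid_hz = c(50, 100),
      band_high_hz = c(100, 240),
      s1_window_s = 0.04,
      resp_band_hz = c(0.07, 1.0),
      max_missing_fraction = 1 / 3
    ),
    split = list(fraction = 0.8, by_subject = FALSE),
    selection = list(threshold = 0.02, num_trees = 500L, per_target = TRUE),
    model = list(
      rf_num_trees = 300L,
      xgb_nrounds = 150L,
      xgb_eta = 0.05,
      xgb_max_depth = 4L,
      bag_n = 20L
    ),
    bootstrap = list(n_comparison = 10000L, n_mad = 1000L)
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML or JSON file, overlays it on [default_config()] (missing
#' fields take their defaults) and validates the result.
#'
#' @param path path to a `.yaml`/`.yml`/`.json` config file, or `NULL` for
#'   pure defaults.
#' @return validated config list with attribute `"hash"`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    cfg <- modify_config(cfg, user)
  }
  validate_config(cfg)
}

#' @keywords internal
#' @noRd
modify_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_config(base[[nm]], user[[nm]])
    } else {
      v <- user[[nm]]
      # preserve names of named numeric defaults when YAML gives a map
      if (!is.null(names(base[[nm]])) && !is.list(base[[nm]]) && is.list(v)) {
        v <- unlist(v)
      }
      base[[nm]] <- v
    }
  }
  base
}

#' Validate a configuration list
#'
#' Checks field presence, ranges and cross-field consistency; the error
#' message names the offending field path.
#' @param cfg config list.
#' @return `cfg`, invisibly augmented with a `"hash"` attribute.
#' @export
validate_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid config at '", field, "': ", why, call. = FALSE)
  }
  fr <- cfg$cohort$class_fractions
  if (is.null(fr) || any(fr < 0) || abs(sum(fr) - 1) > 0.05) {
    fail("cohort.class_fractions", "fractions must be non-negative and sum to 1")
  }
  if (cfg$cohort$n_subjects < 4) fail("cohort.n_subjects", "need at least 4 subjects")
  if (cfg$protocol$obs_spacing_s < 60) {
    fail("protocol.obs_spacing_s", "at least 60 s required between consecutive readings")
  }
  fs <- cfg$signals$fs
  if (any(fs <= 0)) fail("signals.fs", "sampling rates must be positive")
  nyq <- fs[["pcg"]] / 2
  for (b in c("band_low_hz", "band_mid_hz", "band_high_hz")) {
    band <- cfg$features[[b]]
    if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1]) {
      fail(paste0("features.", b), "band must be (low, high) with 0 < low < high")
    }
    if (band[2] >= nyq) {
      fail(paste0("features.", b),
           paste0("band edge ", band[2], " Hz is at or above Nyquist (", nyq, " Hz)"))
    }
  }
  if (!cfg$window$mode %in% c("preceding", "centered")) {
    fail("window.mode", "must be 'preceding' or 'centered'")
  }
  if (cfg$window$window_s > cfg$window$lookback_s) {
    fail("window.window_s", "window cannot exceed the lookback")
  }
  if (cfg$split$fraction <= 0 || cfg$split$fraction >= 1) {
    fail("split.fraction", "must be in (0, 1)")
  }
  if (cfg$selection$threshold < 0 || cfg$selection$threshold >= 1) {
    fail("selection.threshold", "must be in [0, 1)")
  }
  if (is.null(cfg$seed)) fail("seed", "an explicit seed is required")
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

#' Stable hash of a configuration
#'
#' Hash of the canonical JSON serialization, recorded in every stage
#' manifest so outputs can be traced to the exact parameter set.
#' @param cfg config list.
#' @return character scalar.
#' @export
config_hash <- function(cfg) {
  attr(cfg, "hash") <- NULL
  rlang::hash(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA))
}

#' Write a configuration to YAML
#' @param cfg config list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  attr(cfg, "hash") <- NULL
  # yaml drops names on atomic vectors; promote them to maps so the
  # round trip preserves the named defaults (fs, class_fractions, ...)
  promote <- function(x) {
    if (is.list(x)) return(lapply(x, promote))
    if (!is.null(names(x)) && length(names(x)) == length(x)) return(as.list(x))
    x
  }
  yaml::write_yaml(promote(cfg), path)
  invisible(path)
}
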