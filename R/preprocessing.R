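# Signal-quality screening at 1-s resolution and the 300-s lookback /
# 60-s window association rule pairing raw data with each reference
# observation. Bad data is excluded, never repaired.

#' Assess per-second signal quality of a recording
#'
#' A second is unacceptable on a channel if any of:
#' * amplitude saturation — at least `saturation_run` consecutive samples
#'   at or beyond the configured rail;
#' * flatline — sample variance within the second below `variance_floor`;
#' * movement — mean activity-channel amplitude above `movement_threshold`
#'   (flags every channel for that second);
#' * beat inconsistency — on ECG channels, a detected RR interval covering
#'   the second falls outside `rr_range_s`.
#'
#' The composite flag for a second requires every required channel
#' (`ecg1`, `pcg`, `imp1`) to be acceptable.
#'
#' @param rec `mc_recording`.
#' @param cfg pipeline config (uses `quality`).
#' @return object of class `"quality_mask"`: list with `per_channel`
#'   (logical matrix seconds x channels, `TRUE` = acceptable), `composite`
#'   (logical vector), `n_seconds`.
#' @export
assess_quality <- function(rec, cfg = default_config()) {
  q <- cfg$quality
  dur <- recording_duration(rec)
  if (dur < 1) stop("recording shorter than 1 s", call. = FALSE)
  n_sec <- floor(dur)

  per_second_bad <- function(samples, fs, rail) {
    bad <- logical(n_sec)
    # saturation: runs of |x| >= rail with length >= saturation_run
    sat <- abs(samples) >= rail
    if (any(sat)) {
      r <- rle(sat)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      long <- which(r$values & r$lengths >= q$saturation_run)
      for (j in long) {
        s0 <- floor((starts[j] - 1) / fs)
        s1 <- min(n_sec - 1L, floor((ends[j] - 1) / fs))
        bad[(s0:s1) + 1L] <- TRUE
      }
    }
    # flatline: per-second variance below floor
    m <- floor(fs)
    usable <- samples[seq_len(n_sec * m)]
    mat <- matrix(usable, nrow = m)
    v <- colMeans(mat^2) - colMeans(mat)^2
    bad | (v < q$variance_floor)
  }

  required <- intersect(c("ecg1", "ecg2", "pcg", "imp1", "imp2"), names(rec$channels))
  per_channel <- matrix(TRUE, nrow = n_sec, ncol = length(required),
                        dimnames = list(NULL, required))
  rails <- q$saturation_rail
  for (nm in required) {
    ch <- rec$channels[[nm]]
    rail <- if (!is.null(names(rails)) && nm %in% names(rails))
      rails[[nm]] else max(rails)
    per_channel[, nm] <- !per_second_bad(ch$samples, ch$fs, rail)
  }

  # movement: activity channel mean amplitude per second
  if ("activity" %in% names(rec$channels)) {
    act <- rec$channels$activity
    m <- floor(act$fs)
    usable <- abs(act$samples[seq_len(n_sec * m)])
    move <- colMeans(matrix(usable, nrow = m)) > q$movement_threshold
    per_channel[move, ] <- FALSE
  }

  # beat consistency on ecg1: seconds covered by an out-of-range RR interval
  if ("ecg1" %in% names(rec$channels)) {
    ch <- rec$channels$ecg1
    r <- tryCatch(
      detect_r_peak_times(ch$samples, ch$fs, screen = FALSE),
      error = function(e) numeric(0)
    )
    if (length(r) >= 2) {
      rr <- diff(r)
      bad_rr <- which(rr < q$rr_range_s[1] | rr > q$rr_range_s[2])
      for (j in bad_rr) {
        s0 <- max(0L, floor(r[j]))
        s1 <- min(n_sec - 1L, floor(r[j + 1]))
        per_channel[(s0:s1) + 1L, "ecg1"] <- FALSE
      }
    } else {
      per_channel[, "ecg1"] <- FALSE
    }
  }

  composite <- apply(per_channel[, intersect(c("ecg1", "pcg", "imp1"), required),
                                 drop = FALSE], 1L, all)
  structure(list(per_channel = per_channel, composite = as.logical(composite),
                 n_seconds = n_sec),
            class = "quality_mask")
}

#' Associate an acceptable 60-s analysis window with an observation
#'
#' Searches the lookback interval preceding the observation timestamp for a
#' fully acceptable window of `window_s` seconds and returns the latest one
#' (the window closest to the measurement). Windows are half-open
#' `[start, end)` on the 1-s mask grid, with `end <= timestamp` and
#' `start >= timestamp - lookback_s`. If the observation falls earlier than
#' `lookback_s` into the recording, the lookback is truncated to the
#' available data and the result is marked `truncated_lookback`. In
#' `"centered"` mode the single window centered on the timestamp is used if
#' acceptable.
#'
#' @param mask `"quality_mask"` (or a logical per-second composite vector).
#' @param timestamp_s observation time, seconds since recording start.
#' @param cfg pipeline config (uses `window`).
#' @return list of class `"analysis_window"`: `window_start`, `window_end`,
#'   `accepted` (logical), `reason` (`NA` or `"no_acceptable_window"`),
#'   `truncated_lookback`.
#' @export
associate_window <- function(mask, timestamp_s, cfg = default_config()) {
  comp <- if (inherits(mask, "quality_mask")) mask$composite else as.logical(mask)
  W <- as.integer(cfg$window$window_s)
  L <- cfg$window$lookback_s
  n_sec <- length(comp)

  reject <- function(reason, truncated = FALSE) {
    structure(list(window_start = NA_real_, window_end = NA_real_,
                   accepted = FALSE, reason = reason,
                   truncated_lookback = truncated),
              class = "analysis_window")
  }
  accept <- function(s, truncated) {
    structure(list(window_start = as.numeric(s), window_end = as.numeric(s + W),
                   accepted = TRUE, reason = NA_character_,
                   truncated_lookback = truncated),
              class = "analysis_window")
  }

  if (cfg$window$mode == "centered") {
    s <- floor(timestamp_s - W / 2)
    if (s < 0 || s + W > n_sec) return(reject("window_outside_recording"))
    if (all(comp[(s + 1):(s + W)])) return(accept(s, FALSE)) else
      return(reject("no_acceptable_window"))
  }

  s_max <- floor(timestamp_s) - W
  s_min <- ceiling(timestamp_s - L)
  truncated <- s_min < 0
  s_min <- max(0L, s_min)
  s_max <- min(s_max, n_sec - W)
  if (s_max < s_min) return(reject("no_acceptable_window", truncated))

  bad <- cumsum(!comp)
  starts <- seq.int(s_min, s_max)
  # window [s, s+W) acceptable iff no bad seconds among indices s+1 .. s+W
  bad0 <- c(0L, bad)   # prepend so start 0 indexes cleanly
  n_bad <- bad[starts + W] - bad0[starts + 1L]
  ok <- which(n_bad == 0L)
  if (!length(ok)) return(reject("no_acceptable_window", truncated))
  accept(starts[ok[length(ok)]], truncated)
}

#' Extract per-channel sample slices for an analysis window
#'
#' @param rec `mc_recording`.
#' @param window accepted `"analysis_window"`.
#' @return named list of `list(samples, fs, units)` restricted to
#'   `[window_start, window_end)`.
#' @export
window_slices <- function(rec, window) {
  stopifnot(inherits(window, "analysis_window"), isTRUE(window$accepted))
  lapply(rec$channels, function(ch) {
    lo <- floor(window$window_start * ch$fs) + 1L
    hi <- min(length(ch$samples), floor(window$window_end * ch$fs))
    list(samples = ch$samples[lo:hi], fs = ch$fs, units = ch$units)
  })
}

#' Associate windows for a whole observation table
#'
#' Runs [associate_window()] for every observation and returns the results
#' plus a rejection log.
#'
#' @param mask `"quality_mask"`.
#' @param obs observation data frame with `obs_id` and `timestamp_s`.
#' @param cfg pipeline config.
#' @return list: `windows` (named list of `"analysis_window"`), `log`
#'   (data frame `obs_id`, `accepted`, `reason`).
#' @export
associate_windows <- function(mask, obs, cfg = default_config()) {
  windows <- lapply(seq_len(nrow(obs)), function(i) {
    associate_window(mask, obs$timestamp_s[i], cfg)
  })
  names(windows) <- obs$obs_id
  log <- data.frame(
    obs_id = obs$obs_id,
    accepted = vapply(windows, `[[`, logical(1), "accepted"),
    reason = vapply(windows, function(w) {
      if (is.na(w$reason)) "" else w$reason
    }, character(1))
  )
  list(windows = windows, log = log)
}
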