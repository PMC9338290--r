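# Recording/observation containers and their on-disk formats: one CSV per
# channel plus a JSON header (a WFDB-style record layout in plain text),
# and the observation/feature/reference CSV schemas.

RECORDING_CHANNELS <- c("ecg1", "ecg2", "pcg", "imp1", "imp2", "activity")

#' Construct a multichannel recording
#'
#' The in-memory container for a time-aligned session recording. All
#' channels share `start_time` (seconds since session start); each carries
#' its own sampling rate and units.
#'
#' @param channels named list; each element `list(samples =, fs =, units =)`.
#'   Names must be drawn from `ecg1, ecg2, pcg, imp1, imp2, activity`.
#' @param subject_id opaque subject identifier.
#' @param start_time seconds since session start.
#' @return object of class `"mc_recording"`.
#' @export
new_recording <- function(channels, subject_id, start_time = 0) {
  bad <- setdiff(names(channels), RECORDING_CHANNELS)
  if (length(bad)) stop("unknown channel name(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (is.null(ch$fs) || ch$fs <= 0) {
      stop("channel '", nm, "': fs must be positive", call. = FALSE)
    }
    if (length(ch$samples) < 1L) {
      stop("channel '", nm, "': empty samples", call. = FALSE)
    }
  }
  structure(list(channels = channels, subject_id = subject_id,
                 start_time = start_time),
            class = "mc_recording")
}

#' @export
print.mc_recording <- function(x, ...) {
  cat("<mc_recording> subject", x$subject_id, "\n")
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    cat(sprintf("  %-8s %8d samples @ %g Hz (%.1f s) [%s]\n", nm,
                length(ch$samples), ch$fs, length(ch$samples) / ch$fs, ch$units))
  }
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec `mc_recording`.
#' @return numeric scalar (shortest channel duration).
#' @export
recording_duration <- function(rec) {
  min(vapply(rec$channels, function(ch) length(ch$samples) / ch$fs, numeric(1)))
}

#' Write / read a recording
#'
#' On disk a recording is a directory with `header.json` (subject id, start
#' time, per-channel sampling rate, units and sample count) and one
#' `<channel>.csv` of samples per channel. The round trip is lossless to at
#' least 1e-6 relative precision (samples are written with 15 significant
#' digits).
#'
#' @param rec `mc_recording`.
#' @param path directory to create/read.
#' @return `write_recording`: `path` invisibly; `read_recording`: the
#'   reconstructed `mc_recording`.
#' @export
write_recording <- function(rec, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  hdr <- list(
    subject_id = rec$subject_id,
    start_time = rec$start_time,
    channels = lapply(rec$channels, function(ch) {
      list(fs = ch$fs, units = ch$units, n = length(ch$samples))
    })
  )
  jsonlite::write_json(hdr, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(rec$channels)) {
    data.table::fwrite(
      data.table::data.table(value = rec$channels[[nm]]$samples),
      file.path(path, paste0(nm, ".csv"))
    )
  }
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  hp <- file.path(path, "header.json")
  if (!file.exists(hp)) stop("recording format error: missing header.json in ",
                             path, call. = FALSE)
  hdr <- jsonlite::read_json(hp, simplifyVector = FALSE)
  channels <- list()
  for (nm in names(hdr$channels)) {
    meta <- hdr$channels[[nm]]
    if (is.null(meta$fs) || meta$fs <= 0) {
      stop("recording format error in field 'fs' of channel '", nm,
           "': must be positive", call. = FALSE)
    }
    fp <- file.path(path, paste0(nm, ".csv"))
    if (!file.exists(fp)) {
      stop("recording format error: missing channel file '", nm, ".csv'",
           call. = FALSE)
    }
    samples <- data.table::fread(fp)$value
    if (length(samples) != meta$n) {
      stop("recording format error in field 'n' of channel '", nm,
           "': header says ", meta$n, " samples, file has ", length(samples),
           call. = FALSE)
    }
    channels[[nm]] <- list(samples = as.numeric(samples), fs = meta$fs,
                           units = meta$units)
  }
  new_recording(channels, subject_id = hdr$subject_id,
                start_time = hdr$start_time %||% 0)
}

OBSERVATION_COLUMNS <- c("subject_id", "timestamp_s", "condition",
                         "obs1_sbp", "obs1_dbp", "obs2_sbp", "obs2_dbp")

#' Write / read a blood-pressure observation table
#'
#' CSV schema: `subject_id, timestamp_s, condition, obs1_sbp, obs1_dbp,
#' obs2_sbp, obs2_dbp` plus optional device columns (`cuff_sbp`,
#' `cuff_dbp`, `cuff_timestamp_s`) and `obs_id`. Timestamps are seconds
#' since session start (sub-minute resolution is kept; see
#' [minute_truncated()] for the protocol's nearest-minute view). On read,
#' rows with any pressure outside \[40, 300\] mmHg are rejected (dropped
#' with a message listing row numbers) and readings off the 2-mmHg grid
#' produce a warning but are retained.
#'
#' @param obs data frame in the schema above.
#' @param path CSV path.
#' @return `read_observations`: the validated data frame, row order
#'   preserved, with attribute `"rejected_rows"`.
#' @export
write_observations <- function(obs, path) {
  data.table::fwrite(obs, path)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  obs <- as.data.frame(data.table::fread(path))
  miss <- setdiff(OBSERVATION_COLUMNS, names(obs))
  if (length(miss)) {
    stop("observation format error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  pcols <- grep("(sbp|dbp)$", names(obs), value = TRUE)
  pm <- as.matrix(obs[, pcols, drop = FALSE])
  bad <- apply(pm, 1L, function(r) any(!is.na(r) & (r < 40 | r > 300)))
  if (any(bad)) {
    message("rejected ", sum(bad), " observation row(s) with pressures outside ",
            "[40, 300] mmHg: rows ", paste(which(bad), collapse = ", "))
  }
  ocols <- grep("^obs[12]_(sbp|dbp)$", names(obs), value = TRUE)
  og <- as.matrix(obs[!bad, ocols, drop = FALSE])
  if (any(og %% 2 != 0, na.rm = TRUE)) {
    warning("observer reading(s) off the 2-mmHg grid; rows retained")
  }
  out <- obs[!bad, , drop = FALSE]
  attr(out, "rejected_rows") <- which(bad)
  out
}

#' Nearest-minute view of observation timestamps
#'
#' The protocol records measurement times to the nearest minute; storage
#' keeps seconds. This view truncates to whole minutes without altering the
#' stored values.
#' @param timestamp_s numeric seconds.
#' @return integer minutes since session start.
#' @export
minute_truncated <- function(timestamp_s) as.integer(floor(timestamp_s / 60))

#' Write / read a feature matrix with its metadata sidecar
#'
#' The feature matrix is one CSV row per observation (header = feature
#' registry plus identifying columns); a JSON sidecar records the registry
#' and the configuration hash so downstream stages can verify provenance.
#'
#' @param feat data frame of features.
#' @param path CSV path (`.json` sidecar written alongside).
#' @param registry character vector of feature names.
#' @param config_hash hash string from [config_hash()].
#' @return `read_features`: list `features`, `meta`.
#' @export
write_features <- function(feat, path, registry, config_hash = "") {
  data.table::fwrite(feat, path)
  jsonlite::write_json(
    list(registry = registry, config_hash = config_hash,
         n_rows = nrow(feat)),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  feat <- as.data.frame(data.table::fread(path))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else NULL
  list(features = feat, meta = meta)
}
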