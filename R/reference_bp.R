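# Reference-measurement rules: dual-observer reconciliation on the 2-mmHg
# grid, entry BP, JNC 7 classification, and device/reference pairing.

#' Reconcile a dual-observer sphygmomanometer reading
#'
#' Two trained observers read the same cuff simultaneously. When their
#' readings are no more than 4 mmHg apart the mean of the two is the
#' reference value; otherwise the measurement must be retaken and no
#' reference exists. The mean is kept unrounded (the 2-mmHg grid applies to
#' raw readings only), so an odd reference such as 121 mmHg is legitimate.
#'
#' @param o1,o2 observer readings in mmHg (vectorized). Readings off the
#'   2-mmHg grid trigger a warning but are processed.
#' @param max_diff maximum tolerated absolute disagreement, mmHg.
#' @return numeric vector: the mean where reconciled, `NA` where the pair
#'   must be retaken.
#' @export
#' @examples
#' reconcile_observers(120, 124)  # 122
#' reconcile_observers(120, 126)  # NA: retake
reconcile_observers <- function(o1, o2, max_diff = 4) {
  stopifnot(length(o1) == length(o2))
  off_grid <- (o1 %% 2 != 0) | (o2 %% 2 != 0)
  if (any(off_grid, na.rm = TRUE)) {
    warning(sum(off_grid, na.rm = TRUE),
            " reading(s) off the 2-mmHg grid; processed as-is")
  }
  out <- (o1 + o2) / 2
  out[abs(o1 - o2) > max_diff] <- NA_real_
  out
}

#' Entry blood pressure from three seated readings
#'
#' The arithmetic mean of three consecutive seated readings taken at the
#' start of the visit; the entry BP determines the subject's JNC 7 class.
#'
#' @param sbp,dbp numeric vectors of exactly three readings each, mmHg.
#' @return named numeric vector `c(sbp = , dbp = )`.
#' @export
entry_bp <- function(sbp, dbp) {
  if (length(sbp) != 3L || length(dbp) != 3L) {
    stop("entry BP requires exactly three seated reading pairs", call. = FALSE)
  }
  c(sbp = mean(sbp), dbp = mean(dbp))
}

#' JNC 7 blood-pressure classification
#'
#' Classifies pressures into normal / prehypertension / stage 1 / stage 2.
#' Normal requires both SBP < 120 and DBP < 80; the hypertensive classes use
#' or-logic (either pressure qualifies) and when SBP and DBP fall in
#' different classes the higher class wins. Boundary values shared by two
#' class definitions (SBP 160, DBP 100) resolve to the higher class, per
#' JNC 7 convention.
#'
#' @param sbp,dbp pressures in mmHg (vectorized).
#' @return factor with levels `normal`, `prehypertension`, `stage1`, `stage2`.
#' @export
#' @examples
#' classify_jnc7(118, 78)   # normal
#' classify_jnc7(125, 72)   # prehypertension
#' classify_jnc7(132, 96)   # stage1 (DBP dominates)
#' classify_jnc7(165, 70)   # stage2
classify_jnc7 <- function(sbp, dbp) {
  stopifnot(length(sbp) == length(dbp))
  cls <- ifelse(sbp >= 160 | dbp >= 100, "stage2",
         ifelse(sbp >= 140 | dbp >= 90,  "stage1",
         ifelse(sbp >= 120 | dbp >= 80,  "prehypertension", "normal")))
  factor(cls, levels = bp_class_levels())
}

#' @rdname classify_jnc7
#' @export
bp_class_levels <- function() c("normal", "prehypertension", "stage1", "stage2")

#' Reconcile a table of dual-observer readings
#'
#' Applies [reconcile_observers()] to both components of every observation
#' and reports a status per row.
#'
#' @param obs data frame with columns `obs1_sbp`, `obs1_dbp`, `obs2_sbp`,
#'   `obs2_dbp` (and any identifying columns, which are carried through).
#' @return `obs` with added columns `sbp_ref`, `dbp_ref`, `status`
#'   (`"ok"`/`"retake"`) and `reason`.
#' @export
reconcile_reference_table <- function(obs) {
  need <- c("obs1_sbp", "obs1_dbp", "obs2_sbp", "obs2_dbp")
  miss <- setdiff(need, names(obs))
  if (length(miss)) stop("missing observer columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  obs$sbp_ref <- reconcile_observers(obs$obs1_sbp, obs$obs2_sbp)
  obs$dbp_ref <- reconcile_observers(obs$obs1_dbp, obs$obs2_dbp)
  ok <- !is.na(obs$sbp_ref) & !is.na(obs$dbp_ref)
  obs$status <- ifelse(ok, "ok", "retake")
  obs$reason <- ifelse(ok, "", "observer_disagreement_gt_4mmHg")
  obs
}

#' Pair device/model readings with reference measurements
#'
#' Builds the (p_i, y_i) pairs entering MAD/MAPD/RMSE. Two pairing modes:
#'
#' * `"simultaneous"` — the device reading shares its timestamp with a
#'   reconciled reference (the wearable records through cuff inflation, so
#'   its estimate is scored against the simultaneous reference).
#' * `"adjacent_mean"` — the reference is the mean of the two reconciled
#'   references bracketing the device reading in time (sequential devices
#'   such as a wrist cuff; the ISO 81060-2:2019 convention). Readings
#'   without both a preceding and a following reference within
#'   `max_gap_s` are dropped.
#'
#' @param device data frame with columns `timestamp_s` and `value` (the
#'   device/model reading, mmHg); optionally `obs_id`, `condition`.
#' @param reference data frame with columns `timestamp_s` and `value`
#'   (reconciled reference, mmHg); rows with `NA` value are ignored.
#' @param mode `"simultaneous"` or `"adjacent_mean"`.
#' @param max_gap_s for `adjacent_mean`, maximum allowed gap to each
#'   bracketing reference.
#' @param tol_s for `simultaneous`, timestamp matching tolerance.
#' @return data frame of pairs: `p` (device), `y` (reference), plus carried
#'   identifying columns; attribute `"n_dropped"` counts unpaired readings.
#' @export
make_pairs <- function(device, reference,
                       mode = c("simultaneous", "adjacent_mean"),
                       max_gap_s = 150, tol_s = 0.5) {
  mode <- match.arg(mode)
  reference <- reference[!is.na(reference$value), , drop = FALSE]
  reference <- reference[order(reference$timestamp_s), , drop = FALSE]
  keep_cols <- intersect(c("obs_id", "condition"), names(device))
  n_dropped <- 0L
  rows <- vector("list", nrow(device))
  for (i in seq_len(nrow(device))) {
    t <- device$timestamp_s[i]
    y <- NA_real_
    if (mode == "simultaneous") {
      j <- which(abs(reference$timestamp_s - t) <= tol_s)
      if (length(j)) y <- reference$value[j[1]]
    } else {
      before <- reference$timestamp_s < t
      after <- reference$timestamp_s > t
      if (any(before) && any(after)) {
        tb <- max(reference$timestamp_s[before])
        ta <- min(reference$timestamp_s[after])
        if ((t - tb) <= max_gap_s && (ta - t) <= max_gap_s) {
          y <- mean(c(reference$value[reference$timestamp_s == tb][1],
                      reference$value[reference$timestamp_s == ta][1]))
        }
      }
    }
    if (is.na(y) || is.na(device$value[i])) {
      n_dropped <- n_dropped + 1L
    } else {
      r <- data.frame(p = device$value[i], y = y)
      for (k in keep_cols) r[[k]] <- device[[k]][i]
      rows[[i]] <- r
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(p = numeric(0), y = numeric(0))
  attr(out, "n_dropped") <- n_dropped
  out
}
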