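# Stage orchestration: simulate -> extract -> train -> evaluate -> compare.
# Every stage reads its inputs from files and writes its artifacts plus a
# manifest, so stages are independently re-runnable; run_pipeline() chains
# them. All randomness flows from the single config seed.

PIPELINE_STAGES <- c("simulate", "extract", "train", "evaluate", "compare")

#' @keywords internal
#' @noRd
require_artifact <- function(path, produced_by) {
  if (!file.exists(path)) {
    stop("missing artifact '", basename(path), "'; run stage '", produced_by,
         "' first", call. = FALSE)
  }
  path
}

#' @keywords internal
#' @noRd
write_manifest <- function(out_dir, stage, cfg, extra = list()) {
  jsonlite::write_json(
    c(list(stage = stage, config_hash = config_hash(cfg), seed = cfg$seed),
      extra),
    file.path(out_dir, paste0("manifest_", stage, ".json")),
    auto_unbox = TRUE, digits = NA
  )
}

#' Simulate stage: cohort, recordings and observations
#'
#' Generates the stratified cohort and, per subject, a full-session
#' multichannel recording with scheduled dual-observer (plus wrist-cuff)
#' readings. Writes `cohort.csv`, `observations.csv`, `ground_truth.csv`
#' (planted parameters, for diagnostics only — never consumed by later
#' stages), and one recording directory per subject under `recordings/`.
#'
#' @param cfg validated pipeline config.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the observation table.
#' @export
stage_simulate <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(cfg$cohort$n_subjects, cfg$cohort$class_fractions,
                            seed = derive_seed(cfg$seed, 1L))
  data.table::fwrite(cohort, file.path(out_dir, "cohort.csv"))
  sched <- session_schedule(cfg)
  all_obs <- list(); all_gt <- list()
  for (i in seq_len(nrow(cohort))) {
    subject <- cohort[i, ]
    ses <- synthesize_recording(subject, cfg, seed = derive_seed(cfg$seed, 1000L + i),
                                sched = sched)
    write_recording(ses$recording,
                    file.path(out_dir, "recordings", subject$subject_id))
    all_obs[[i]] <- ses$observations
    all_gt[[i]] <- ses$ground_truth
  }
  obs <- do.call(rbind, all_obs)
  write_observations(obs, file.path(out_dir, "observations.csv"))
  data.table::fwrite(do.call(rbind, all_gt), file.path(out_dir, "ground_truth.csv"))
  write_manifest(out_dir, "simulate", cfg,
                 list(n_subjects = nrow(cohort), n_observations = nrow(obs)))
  invisible(obs)
}

#' Extract stage: quality screening, window association, features
#'
#' For each subject: assess per-second quality, associate a 60-s acceptable
#' window with each observation under the 300-s lookback rule, extract the
#' feature vector on accepted windows, and reconcile the dual-observer
#' readings into reference values. Writes `features.csv` (+ JSON sidecar),
#' `references.csv` and `rejections.csv`.
#'
#' @inheritParams stage_simulate
#' @return invisibly, the feature table.
#' @export
stage_extract <- function(cfg, out_dir) {
  obs <- read_observations(
    require_artifact(file.path(out_dir, "observations.csv"), "simulate"))
  cohort <- as.data.frame(data.table::fread(
    require_artifact(file.path(out_dir, "cohort.csv"), "simulate")))
  feat_rows <- list(); rej_rows <- list()
  for (sid in unique(obs$subject_id)) {
    rec <- read_recording(
      require_artifact(file.path(out_dir, "recordings", sid), "simulate"))
    subject <- cohort[cohort$subject_id == sid, ]
    sub_obs <- obs[obs$subject_id == sid, ]
    mask <- assess_quality(rec, cfg)
    assoc <- associate_windows(mask, sub_obs, cfg)
    for (j in seq_len(nrow(sub_obs))) {
      w <- assoc$windows[[j]]
      oid <- sub_obs$obs_id[j]
      if (!w$accepted) {
        rej_rows[[length(rej_rows) + 1L]] <-
          data.frame(obs_id = oid, reason = w$reason)
        next
      }
      fv <- build_feature_vector(window_slices(rec, w), subject, cfg)
      if (!is.data.frame(fv)) {
        rej_rows[[length(rej_rows) + 1L]] <-
          data.frame(obs_id = oid, reason = attr(fv, "reason"))
        next
      }
      fv <- cbind(data.frame(obs_id = oid, subject_id = sid,
                             condition = sub_obs$condition[j],
                             timestamp_s = sub_obs$timestamp_s[j],
                             window_start = w$window_start,
                             window_end = w$window_end), fv)
      feat_rows[[length(feat_rows) + 1L]] <- fv
    }
  }
  features <- do.call(rbind, feat_rows)
  write_features(features, file.path(out_dir, "features.csv"),
                 registry = feature_registry(), config_hash = config_hash(cfg))
  rejections <- if (length(rej_rows)) do.call(rbind, rej_rows) else
    data.frame(obs_id = character(0), reason = character(0))
  data.table::fwrite(rejections, file.path(out_dir, "rejections.csv"))

  refs <- reconcile_reference_table(obs)
  data.table::fwrite(
    refs[, c("obs_id", "subject_id", "timestamp_s", "condition",
             "sbp_ref", "dbp_ref", "status", "reason")],
    file.path(out_dir, "references.csv"))
  write_manifest(out_dir, "extract", cfg,
                 list(n_features = nrow(features), n_rejected = nrow(rejections)))
  invisible(features)
}

#' Train stage: split, feature selection, model fitting
#'
#' Joins features with reconciled references, splits observations 80/20,
#' runs impurity-based selection per target on the training rows and fits
#' the SBP/DBP signal ensembles plus demographics baselines. Writes
#' `split.csv`, `selection.json` and `models.rds`.
#'
#' @inheritParams stage_simulate
#' @return invisibly, the fitted `"bp_models"`.
#' @export
stage_train <- function(cfg, out_dir) {
  features <- read_features(
    require_artifact(file.path(out_dir, "features.csv"), "extract"))$features
  refs <- as.data.frame(data.table::fread(
    require_artifact(file.path(out_dir, "references.csv"), "extract")))
  dat <- merge(features, refs[refs$status == "ok",
                              c("obs_id", "sbp_ref", "dbp_ref")], by = "obs_id")
  dat <- dat[order(dat$obs_id), ]
  split <- split_dataset(nrow(dat), fraction = cfg$split$fraction,
                         seed = derive_seed(cfg$seed, 3L),
                         subject_ids = dat$subject_id,
                         by_subject = isTRUE(cfg$split$by_subject))
  data.table::fwrite(data.frame(obs_id = dat$obs_id, split = split),
                     file.path(out_dir, "split.csv"))
  tr <- dat[split == "train", ]
  enc <- encode_features(tr, feature_registry())
  sel_sbp <- select_features(enc$x, tr$sbp_ref, threshold = cfg$selection$threshold,
                             seed = derive_seed(cfg$seed, 41L),
                             num_trees = cfg$selection$num_trees)
  sel_dbp <- select_features(enc$x, tr$dbp_ref, threshold = cfg$selection$threshold,
                             seed = derive_seed(cfg$seed, 42L),
                             num_trees = cfg$selection$num_trees)
  jsonlite::write_json(
    list(sbp = list(selected = sel_sbp$selected,
                    importance = as.list(sel_sbp$importance)),
         dbp = list(selected = sel_dbp$selected,
                    importance = as.list(sel_dbp$importance))),
    file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)
  models <- train_models(
    tr, data.frame(sbp = tr$sbp_ref, dbp = tr$dbp_ref),
    selected = list(sbp = sel_sbp$selected, dbp = sel_dbp$selected),
    cfg = cfg, seed = derive_seed(cfg$seed, 5L))
  saveRDS(models, file.path(out_dir, "models.rds"))
  write_manifest(out_dir, "train", cfg,
                 list(n_train = sum(split == "train"),
                      n_test = sum(split == "test"),
                      selected_sbp = sel_sbp$selected,
                      selected_dbp = sel_dbp$selected))
  invisible(models)
}

#' Evaluate stage: predictions, stratified metrics, agreement statistics
#'
#' Predicts SBP/DBP on every observation with the signal models and the
#' baselines, scores them against the reconciled references (simultaneous
#' pairing), scores the wrist-cuff column with adjacent-mean pairing, and
#' writes the condition-stratified report with Bland-Altman statistics and
#' bootstrap MAD confidence intervals to `evaluation.json` (plus
#' `predictions.csv` and `metrics.csv`).
#'
#' @inheritParams stage_simulate
#' @return invisibly, the evaluation list.
#' @export
stage_evaluate <- function(cfg, out_dir) {
  models <- readRDS(require_artifact(file.path(out_dir, "models.rds"), "train"))
  features <- read_features(
    require_artifact(file.path(out_dir, "features.csv"), "extract"))$features
  refs <- as.data.frame(data.table::fread(file.path(out_dir, "references.csv")))
  split_df <- as.data.frame(data.table::fread(
    require_artifact(file.path(out_dir, "split.csv"), "train")))
  obs <- read_observations(file.path(out_dir, "observations.csv"))

  dat <- merge(features, refs[refs$status == "ok",
                              c("obs_id", "sbp_ref", "dbp_ref")], by = "obs_id")
  dat <- merge(dat, split_df, by = "obs_id")
  dat <- dat[order(dat$obs_id), ]

  preds <- data.frame(
    obs_id = dat$obs_id, split = dat$split, condition = dat$condition,
    sbp_ref = dat$sbp_ref, dbp_ref = dat$dbp_ref,
    sbp_hat = predict(models$sbp, dat),
    dbp_hat = predict(models$dbp, dat),
    sbp_hat_baseline = predict(models$baseline_sbp, dat),
    dbp_hat_baseline = predict(models$baseline_dbp, dat)
  )
  data.table::fwrite(preds, file.path(out_dir, "predictions.csv"))

  long <- function(p, y, target, device) {
    data.frame(p = p, y = y, target = target, condition = preds$condition,
               split = preds$split, device = device)
  }
  pairs <- rbind(
    long(preds$sbp_hat, preds$sbp_ref, "sbp", "model"),
    long(preds$dbp_hat, preds$dbp_ref, "dbp", "model"),
    long(preds$sbp_hat_baseline, preds$sbp_ref, "sbp", "baseline"),
    long(preds$dbp_hat_baseline, preds$dbp_ref, "dbp", "baseline")
  )

  # wrist cuff: sequential reading scored against the adjacent-mean reference
  if ("cuff_sbp" %in% names(obs)) {
    refs_ok <- refs[refs$status == "ok", ]
    split_of <- stats::setNames(preds$split, preds$obs_id)
    cuff_rows <- list()
    for (tg in c("sbp", "dbp")) {
      for (sid in unique(obs$subject_id)) {
        so <- obs[obs$subject_id == sid, ]
        sr <- refs_ok[refs_ok$subject_id == sid, ]
        device <- data.frame(obs_id = so$obs_id,
                             timestamp_s = so$cuff_timestamp_s,
                             value = so[[paste0("cuff_", tg)]],
                             condition = so$condition)
        reference <- data.frame(timestamp_s = sr$timestamp_s,
                                value = sr[[paste0(tg, "_ref")]])
        pr <- make_pairs(device, reference, mode = "adjacent_mean",
                         max_gap_s = cfg$protocol$obs_spacing_s * 1.5)
        if (nrow(pr) == 0) next
        pr$target <- tg
        pr$split <- unname(split_of[pr$obs_id])
        pr$device <- "cuff"
        cuff_rows[[length(cuff_rows) + 1L]] <-
          pr[!is.na(pr$split), c("p", "y", "target", "condition", "split", "device")]
      }
    }
    if (length(cuff_rows)) pairs <- rbind(pairs, do.call(rbind, cuff_rows))
  }

  report <- stratified_report(pairs, extra_by = "device")
  data.table::fwrite(report$metrics, file.path(out_dir, "metrics.csv"))

  test <- preds[preds$split == "test", ]
  mad_ci <- list(
    sbp = as.list(c(estimate = mad_error(test$sbp_hat, test$sbp_ref),
                    bootstrap_mad_ci(test$sbp_hat, test$sbp_ref,
                                     n_iterations = cfg$bootstrap$n_mad,
                                     seed = derive_seed(cfg$seed, 7L)))),
    dbp = as.list(c(estimate = mad_error(test$dbp_hat, test$dbp_ref),
                    bootstrap_mad_ci(test$dbp_hat, test$dbp_ref,
                                     n_iterations = cfg$bootstrap$n_mad,
                                     seed = derive_seed(cfg$seed, 8L))))
  )
  evaluation <- list(
    config_hash = config_hash(cfg), seed = cfg$seed,
    n_train = sum(preds$split == "train"), n_test = sum(preds$split == "test"),
    metrics = report$metrics,
    bland_altman = report$bland_altman,
    test_mad_ci = mad_ci
  )
  jsonlite::write_json(evaluation, file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  write_manifest(out_dir, "evaluate", cfg, list(n_pairs = nrow(pairs)))
  invisible(evaluation)
}

#' Compare stage: paired-bootstrap RMSE comparison on the test split
#'
#' Compares the signal model against the demographics baseline per target
#' with the paired bootstrap and writes `comparison.json`.
#'
#' @inheritParams stage_simulate
#' @return invisibly, the comparison list.
#' @export
stage_compare <- function(cfg, out_dir) {
  preds <- as.data.frame(data.table::fread(
    require_artifact(file.path(out_dir, "predictions.csv"), "evaluate")))
  test <- preds[preds$split == "test", ]
  cmp <- list(
    sbp = bootstrap_rmse_comparison(test$sbp_hat, test$sbp_hat_baseline,
                                    test$sbp_ref,
                                    n_resamples = cfg$bootstrap$n_comparison,
                                    seed = derive_seed(cfg$seed, 9L)),
    dbp = bootstrap_rmse_comparison(test$dbp_hat, test$dbp_hat_baseline,
                                    test$dbp_ref,
                                    n_resamples = cfg$bootstrap$n_comparison,
                                    seed = derive_seed(cfg$seed, 10L))
  )
  jsonlite::write_json(lapply(cmp, unclass),
                       file.path(out_dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "compare", cfg, list(n_test = nrow(test)))
  invisible(cmp)
}

#' Run the pipeline end to end
#'
#' Chains the requested stages in order on one output directory. Any stage
#' error propagates (a missing upstream artifact names the stage to run).
#'
#' @param config a config list from [load_config()]/[default_config()], or
#'   a path to a YAML/JSON config file.
#' @param out_dir output directory.
#' @param stages subset of `simulate, extract, train, evaluate, compare`
#'   (default: all, in order).
#' @param seed optional override of the config seed.
#' @return invisibly, a list with the evaluation and comparison results
#'   (when those stages ran).
#' @export
run_pipeline <- function(config = NULL, out_dir, stages = PIPELINE_STAGES,
                         seed = NULL) {
  cfg <- if (is.character(config)) load_config(config) else
    validate_config(config %||% default_config())
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  out <- list()
  for (st in stages) {
    res <- switch(st,
      simulate = stage_simulate(cfg, out_dir),
      extract = stage_extract(cfg, out_dir),
      train = stage_train(cfg, out_dir),
      evaluate = stage_evaluate(cfg, out_dir),
      compare = stage_compare(cfg, out_dir)
    )
    if (st %in% c("evaluate", "compare")) out[[st]] <- res
  }
  invisible(out)
}

#' Demo configuration
#'
#' The shipped demo parameter set: the study's stratification and protocol
#' with a 40-subject cohort so a complete run finishes in minutes.
#' @param seed seed to embed.
#' @return validated config.
#' @export
demo_config <- function(seed = 20260101L) {
  cfg <- default_config(n_subjects = 40)
  cfg$seed <- as.integer(seed)
  validate_config(cfg)
}
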