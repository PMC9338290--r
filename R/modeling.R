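# Dataset splitting, impurity-based feature selection, the seeded
# heterogeneous regression-tree ensembles for SBP/DBP and the
# demographics-only baseline.

#' Observation-level train/test split
#'
#' A seeded uniform permutation assigns the first `floor(fraction * n)`
#' observations to training and the rest to test. With `subject_ids`
#' supplied and `by_subject = TRUE` whole subjects are assigned instead
#' (for leakage-sensitivity experiments); the observation split remains the
#' default, matching the study design.
#'
#' @param n_rows number of observations (>= 5).
#' @param fraction training fraction (default 0.8).
#' @param seed integer seed.
#' @param subject_ids optional vector of per-row subject ids.
#' @param by_subject split at subject level.
#' @return character vector of `"train"`/`"test"` labels, length `n_rows`.
#' @export
#' @examples
#' table(split_dataset(1686, seed = 1))  # 1348 train, 338 test
split_dataset <- function(n_rows, fraction = 0.8, seed = 1L,
                          subject_ids = NULL, by_subject = FALSE) {
  if (n_rows < 5) stop("need at least 5 rows to split", call. = FALSE)
  set.seed(seed)
  labels <- rep("test", n_rows)
  if (by_subject) {
    if (is.null(subject_ids)) stop("by_subject split needs subject_ids", call. = FALSE)
    subj <- unique(subject_ids)
    n_train_subj <- floor(fraction * length(subj))
    train_subj <- sample(subj)[seq_len(n_train_subj)]
    labels[subject_ids %in% train_subj] <- "train"
  } else {
    n_train <- floor(fraction * n_rows)
    labels[sample.int(n_rows)[seq_len(n_train)]] <- "train"
  }
  labels
}

#' Encode a feature table into a numeric model matrix
#'
#' Registry features become numeric columns; a feature with any missing
#' value in the encoding reference gains a companion 0/1 indicator column
#' (`miss_<name>`) and its missing entries are median-imputed. Imputation
#' medians and the indicator set are learned once (on training data) and
#' reapplied verbatim to new rows.
#'
#' @param df data frame containing the registry columns.
#' @param feature_names registry subset to encode.
#' @param encoder `NULL` to learn the encoding from `df`, or a previously
#'   returned encoder to reapply.
#' @return list: `x` (numeric data frame), `encoder` (medians + indicator
#'   set).
#' @export
encode_features <- function(df, feature_names = feature_registry(),
                            encoder = NULL) {
  miss <- setdiff(feature_names, names(df))
  if (length(miss)) stop("feature table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  vals <- df[, feature_names, drop = FALSE]
  for (nm in feature_names) {
    v <- as.numeric(vals[[nm]])
    v[!is.finite(v)] <- NA_real_
    vals[[nm]] <- v
  }
  if (is.null(encoder)) {
    medians <- vapply(vals, function(v) {
      m <- stats::median(v, na.rm = TRUE)
      if (is.na(m)) 0 else m
    }, numeric(1))
    flagged <- feature_names[vapply(vals, anyNA, logical(1))]
    encoder <- list(medians = medians, flagged = flagged)
  }
  x <- vals
  for (nm in encoder$flagged) {
    if (nm %in% names(x)) {
      x[[paste0("miss_", nm)]] <- as.numeric(is.na(x[[nm]]))
    }
  }
  for (nm in feature_names) {
    na <- is.na(x[[nm]])
    if (any(na)) x[[nm]][na] <- encoder$medians[[nm]]
  }
  list(x = x, encoder = encoder)
}

#' Impurity-based feature selection
#'
#' Fits a seeded random-forest regressor on all supplied features,
#' normalizes the impurity importances to sum to 1, and keeps features
#' whose relative importance exceeds the threshold (study rule: more than
#' 2% overall relative importance). Demographics compete on equal terms —
#' eligible but never forced.
#'
#' @param x numeric feature data frame (from [encode_features()]).
#' @param y numeric target (mmHg).
#' @param threshold relative-importance cutoff (default 0.02).
#' @param seed integer seed.
#' @param num_trees forest size.
#' @return list: `selected` (names), `importance` (named, sums to 1).
#' @export
select_features <- function(x, y, threshold = 0.02, seed = 1L,
                            num_trees = 500L) {
  if (nrow(x) < 50) stop("need at least 50 training rows for selection",
                         call. = FALSE)
  if (stats::var(y) == 0) stop("degenerate target: zero variance", call. = FALSE)
  rf <- ranger::ranger(
    x = x, y = y, num.trees = num_trees, importance = "impurity",
    seed = seed, num.threads = 1L, respect.unordered.factors = TRUE
  )
  imp <- rf$variable.importance
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)
  list(selected = names(imp)[imp > threshold], importance = imp)
}

#' @keywords internal
#' @noRd
fit_tree_ensemble <- function(x, y, cfg_model, seed) {
  xm <- as.matrix(x)
  rf <- ranger::ranger(x = x, y = y, num.trees = cfg_model$rf_num_trees,
                       seed = seed, num.threads = 1L)
  set.seed(derive_seed(seed, 101L))
  xgb <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = cfg_model$xgb_eta,
                  max_depth = cfg_model$xgb_max_depth, nthread = 1,
                  subsample = 0.8, colsample_bytree = 0.8),
    data = xgboost::xgb.DMatrix(xm, label = y),
    nrounds = cfg_model$xgb_nrounds, verbose = 0
  )
  set.seed(derive_seed(seed, 202L))
  dat <- cbind(data.frame(.y = y), x)
  bag <- lapply(seq_len(cfg_model$bag_n), function(i) {
    idx <- sample.int(nrow(dat), replace = TRUE)
    rpart::rpart(.y ~ ., data = dat[idx, , drop = FALSE],
                 control = rpart::rpart.control(cp = 0.001, minsplit = 10,
                                                xval = 0))
  })
  list(rf = rf, xgb_raw = xgboost::xgb.save.raw(xgb), bag = bag)
}

#' Train the SBP/DBP signal models and the demographics baseline
#'
#' Each model is a fixed, seeded, heterogeneous ensemble of tree-based
#' regressors — a random forest, a gradient-boosted tree model and bagged
#' regression trees — whose predictions are averaged. The baseline uses
#' only the demographics (age, sex, height, weight) with the same
#' hyperparameters and training rows. Identical data, config and seed give
#' identical models.
#'
#' @param features feature data frame (registry columns, may contain NA —
#'   encoded internally).
#' @param targets data frame with numeric `sbp` and `dbp` columns aligned
#'   to `features`.
#' @param selected named list `list(sbp = ..., dbp = ...)` of selected
#'   feature names (from [select_features()]); `NULL` selects everything.
#' @param cfg pipeline config.
#' @param seed integer seed.
#' @return list of class `"bp_models"`: elements `sbp`, `dbp`,
#'   `baseline_sbp`, `baseline_dbp`, each a `"bp_ensemble"`.
#' @export
train_models <- function(features, targets, selected = NULL,
                         cfg = default_config(), seed = 1L) {
  stopifnot(nrow(features) == nrow(targets))
  fit_one <- function(target_name, feature_names, tag, seed_off) {
    y <- targets[[target_name]]
    if (anyNA(y)) stop("NA in target '", target_name, "'", call. = FALSE)
    enc <- encode_features(features, feature_names)
    keep <- if (is.null(selected[[tag]])) names(enc$x) else
      intersect(names(enc$x), union(selected[[tag]],
                                    paste0("miss_", selected[[tag]])))
    x <- enc$x[, keep, drop = FALSE]
    if (anyNA(x)) stop("NA left in model matrix after encoding", call. = FALSE)
    members <- fit_tree_ensemble(x, y, cfg$model, derive_seed(seed, seed_off))
    structure(list(target = target_name, feature_names = keep,
                   base_features = feature_names, encoder = enc$encoder,
                   members = members, seed = seed,
                   config_hash = config_hash(cfg)),
              class = "bp_ensemble")
  }
  structure(list(
    sbp = fit_one("sbp", feature_registry(), "sbp", 1L),
    dbp = fit_one("dbp", feature_registry(), "dbp", 2L),
    baseline_sbp = fit_one("sbp", demographic_features(), "baseline", 3L),
    baseline_dbp = fit_one("dbp", demographic_features(), "baseline", 4L)
  ), class = "bp_models")
}

#' Predict blood pressure from feature rows
#'
#' @param object `"bp_ensemble"`.
#' @param newdata data frame containing the model's base features (registry
#'   columns used at training).
#' @param ... unused.
#' @return numeric vector of mmHg estimates.
#' @export
predict.bp_ensemble <- function(object, newdata, ...) {
  miss <- setdiff(object$base_features, names(newdata))
  if (length(miss)) {
    stop("prediction error: missing selected feature(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  enc <- encode_features(newdata, object$base_features, encoder = object$encoder)
  x <- enc$x
  for (nm in setdiff(object$feature_names, names(x))) x[[nm]] <- 0
  x <- x[, object$feature_names, drop = FALSE]
  p_rf <- stats::predict(object$members$rf, data = x,
                         num.threads = 1L)$predictions
  xgb <- xgboost::xgb.load.raw(object$members$xgb_raw)
  p_xgb <- stats::predict(xgb, as.matrix(x))
  p_bag <- rowMeans(vapply(object$members$bag,
                           function(m) stats::predict(m, newdata = x),
                           numeric(nrow(x))))
  unname((p_rf + p_xgb + p_bag) / 3)
}

#' @export
print.bp_ensemble <- function(x, ...) {
  cat("<bp_ensemble> target:", x$target, "|", length(x$feature_names),
      "features | seed", x$seed, "\n")
  invisible(x)
}
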