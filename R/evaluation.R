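# Device-evaluation statistics: MAD / MAPD / RMSE, condition-stratified
# reports, Bland-Altman agreement, the paired-bootstrap RMSE model
# comparison and bootstrap MAD confidence intervals.

#' Mean absolute difference, percentage difference and RMSE
#'
#' For device/model readings `p` and reference readings `y` (both mmHg):
#' `MAD = sum(|p - y|) / n`, `MAPD = sum(100 |p - y| / y) / n` (percent),
#' `RMSE = sqrt(sum((p - y)^2) / n)`. RMSE is never below MAD
#' (power-mean inequality).
#'
#' @param p device or model readings, mmHg.
#' @param y reference readings, mmHg.
#' @return numeric scalar.
#' @export
mad_error <- function(p, y) {
  check_pairs(p, y)
  mean(abs(p - y))
}

#' @rdname mad_error
#' @export
mapd_error <- function(p, y) {
  check_pairs(p, y)
  if (any(y == 0)) stop("MAPD undefined: reference contains zero", call. = FALSE)
  mean(100 * abs(p - y) / y)
}

#' @rdname mad_error
#' @export
rmse_error <- function(p, y) {
  check_pairs(p, y)
  sqrt(mean((p - y)^2))
}

#' @keywords internal
#' @noRd
check_pairs <- function(p, y) {
  if (length(p) == 0L) stop("empty pair set", call. = FALSE)
  if (length(p) != length(y)) stop("p and y differ in length", call. = FALSE)
  if (anyNA(p) || anyNA(y)) stop("pairs contain NA", call. = FALSE)
  invisible(TRUE)
}

#' Bland-Altman agreement statistics
#'
#' Differences are `p - y`; limits of agreement are the mean difference
#' +/- 1.96 standard deviations. The Pearson correlation of `p` with `y`
#' accompanies the scatter view.
#'
#' @inheritParams mad_error
#' @return named list: `mean_diff`, `sd_diff`, `loa_lower`, `loa_upper`,
#'   `correlation`, `n`.
#' @export
bland_altman <- function(p, y) {
  check_pairs(p, y)
  d <- p - y
  sd_d <- stats::sd(d)
  list(mean_diff = mean(d), sd_diff = sd_d,
       loa_lower = mean(d) - 1.96 * sd_d, loa_upper = mean(d) + 1.96 * sd_d,
       correlation = if (length(p) > 2 && stats::sd(p) > 0 && stats::sd(y) > 0)
         stats::cor(p, y) else NA_real_,
       n = length(p))
}

#' Condition-stratified performance report
#'
#' Computes MAD, MAPD and RMSE per target x stratum x split, where strata
#' are `overall` plus each protocol condition, and appends Bland-Altman
#' statistics on the test split per target. Empty cells are reported with
#' `n = 0` and absent metrics.
#'
#' @param pairs data frame with columns `p`, `y`, `target` (`"sbp"`/
#'   `"dbp"`), `condition`, `split` (`"train"`/`"test"`); extra columns
#'   (e.g. `device`) are used as additional grouping keys when named in
#'   `extra_by`.
#' @param extra_by optional extra grouping column names.
#' @return list of class `"metrics_report"`: `metrics` (long data frame),
#'   `bland_altman` (per target/test split).
#' @export
stratified_report <- function(pairs, extra_by = character(0)) {
  need <- c("p", "y", "target", "condition", "split")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) stop("pairs lack column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  strata <- c("overall", unique(as.character(pairs$condition)))
  groups <- expand.grid(target = unique(pairs$target),
                        stratum = strata,
                        split = unique(pairs$split),
                        stringsAsFactors = FALSE)
  extra_groups <- if (length(extra_by)) {
    unique(pairs[, extra_by, drop = FALSE])
  } else data.frame(.dummy = 1)
  rows <- list()
  for (g in seq_len(nrow(groups))) {
    for (e in seq_len(nrow(extra_groups))) {
      sel <- pairs$target == groups$target[g] & pairs$split == groups$split[g]
      if (groups$stratum[g] != "overall") {
        sel <- sel & pairs$condition == groups$stratum[g]
      }
      if (length(extra_by)) {
        for (nm in extra_by) sel <- sel & pairs[[nm]] == extra_groups[[nm]][e]
      }
      sub <- pairs[sel, , drop = FALSE]
      row <- data.frame(target = groups$target[g], stratum = groups$stratum[g],
                        split = groups$split[g], n = nrow(sub),
                        mad = NA_real_, mapd = NA_real_, rmse = NA_real_)
      if (length(extra_by)) for (nm in extra_by) row[[nm]] <- extra_groups[[nm]][e]
      if (nrow(sub) > 0) {
        row$mad <- mad_error(sub$p, sub$y)
        row$mapd <- mapd_error(sub$p, sub$y)
        row$rmse <- rmse_error(sub$p, sub$y)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  metrics <- do.call(rbind, rows)

  ba_rows <- list()
  test <- pairs[pairs$split == "test", , drop = FALSE]
  for (tg in unique(test$target)) {
    for (e in seq_len(nrow(extra_groups))) {
      sel <- test$target == tg
      if (length(extra_by)) {
        for (nm in extra_by) sel <- sel & test[[nm]] == extra_groups[[nm]][e]
      }
      sub <- test[sel, , drop = FALSE]
      if (nrow(sub) < 3) next
      ba <- bland_altman(sub$p, sub$y)
      row <- cbind(data.frame(target = tg), as.data.frame(ba))
      if (length(extra_by)) for (nm in extra_by) row[[nm]] <- extra_groups[[nm]][e]
      ba_rows[[length(ba_rows) + 1L]] <- row
    }
  }
  structure(list(metrics = metrics,
                 bland_altman = if (length(ba_rows)) do.call(rbind, ba_rows)
                                else NULL),
            class = "metrics_report")
}

#' Paired-bootstrap RMSE model comparison
#'
#' Draws `n_resamples` bootstrap samples of the test observations (each of
#' the full test-set size, with replacement), using the *same* indices for
#' both models in every resample, and computes each model's RMSE and their
#' difference (model - baseline). Percentile 95% confidence intervals are
#' the 2.5/97.5 quantiles of the resampled statistics. The superiority
#' criterion is an upper 95% confidence bound of the difference below
#' 0 mmHg; the p-value is the fraction of resamples in which the
#' difference was >= 0 (floored at `1/n_resamples`).
#'
#' @param p_model,p_baseline predictions of the two models on the same test
#'   observations, mmHg.
#' @param y reference values, mmHg.
#' @param n_resamples number of bootstrap resamples (default 10000).
#' @param seed integer seed.
#' @return list of class `"bootstrap_comparison"`: `model_rmse`,
#'   `baseline_rmse`, `diff_rmse` (each `c(estimate, lower, upper)`),
#'   `p_value`, `superior`, `n_resamples`, `n`, `seed`.
#' @export
bootstrap_rmse_comparison <- function(p_model, p_baseline, y,
                                      n_resamples = 10000L, seed = 1L) {
  check_pairs(p_model, y)
  if (length(p_baseline) != length(y)) {
    stop("model and baseline predictions must cover the same observations",
         call. = FALSE)
  }
  n <- length(y)
  e_m <- (p_model - y)^2
  e_b <- (p_baseline - y)^2
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_resamples, replace = TRUE), nrow = n)
  rmse_m <- sqrt(colMeans(matrix(e_m[idx], nrow = n)))
  rmse_b <- sqrt(colMeans(matrix(e_b[idx], nrow = n)))
  d <- rmse_m - rmse_b
  ci <- function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE)
  p_val <- max(mean(d >= 0), 1 / n_resamples)
  structure(list(
    model_rmse = c(estimate = sqrt(mean(e_m)), ci_lower = ci(rmse_m)[1],
                   ci_upper = ci(rmse_m)[2]),
    baseline_rmse = c(estimate = sqrt(mean(e_b)), ci_lower = ci(rmse_b)[1],
                      ci_upper = ci(rmse_b)[2]),
    diff_rmse = c(estimate = sqrt(mean(e_m)) - sqrt(mean(e_b)),
                  ci_lower = ci(d)[1], ci_upper = ci(d)[2]),
    p_value = p_val,
    superior = unname(ci(d)[2] < 0),
    n_resamples = n_resamples, n = n, seed = seed
  ), class = "bootstrap_comparison")
}

#' @export
print.bootstrap_comparison <- function(x, ...) {
  f <- function(v) sprintf("%.2f (%.2f, %.2f)", v[1], v[2], v[3])
  cat("Paired bootstrap RMSE comparison (", x$n_resamples, " resamples, n = ",
      x$n, ")\n", sep = "")
  cat("  model:    ", f(x$model_rmse), "mmHg\n")
  cat("  baseline: ", f(x$baseline_rmse), "mmHg\n")
  cat("  diff:     ", f(x$diff_rmse), sprintf("mmHg, p = %.4f", x$p_value), "\n")
  cat("  superior: ", x$superior, "\n")
  invisible(x)
}

#' Bootstrap confidence interval for the MAD
#'
#' Percentile 95% interval of the MAD over `n_iterations` resamples with
#' replacement, each of the full pair-set size.
#'
#' @inheritParams mad_error
#' @param n_iterations number of resamples (default 1000).
#' @param seed integer seed.
#' @return named numeric `c(lower, upper)`, with attribute `"estimate"`.
#' @export
bootstrap_mad_ci <- function(p, y, n_iterations = 1000L, seed = 1L) {
  check_pairs(p, y)
  if (length(p) < 10) stop("need at least 10 pairs", call. = FALSE)
  ae <- abs(p - y)
  n <- length(ae)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_iterations, replace = TRUE), nrow = n)
  mads <- colMeans(matrix(ae[idx], nrow = n))
  out <- stats::quantile(mads, c(0.025, 0.975), names = FALSE)
  names(out) <- c("lower", "upper")
  attr(out, "estimate") <- mean(ae)
  out
}
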