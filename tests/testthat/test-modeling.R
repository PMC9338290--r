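test_that("the 80/20 split follows the floor rule and is a seeded partition", {
  s <- split_dataset(1686, seed = 1)
  expect_equal(sum(s == "train"), 1348)
  expect_equal(sum(s == "test"), 338)
  expect_equal(table(split_dataset(10, seed = 2))[["train"]], 8)
  expect_identical(split_dataset(100, seed = 3), split_dataset(100, seed = 3))
  expect_false(identical(split_dataset(100, seed = 3), split_dataset(100, seed = 4)))
  # partition: every row labeled, sizes exact for arbitrary n
  for (n in c(5, 37, 211)) {
    s <- split_dataset(n, seed = 5)
    expect_equal(length(s), n)
    expect_equal(sum(s == "train"), floor(0.8 * n))
  }
  expect_error(split_dataset(4), "at least 5")
})

test_that("subject-level split keeps subjects intact", {
  ids <- rep(sprintf("S%02d", 1:10), each = 12)
  s <- split_dataset(length(ids), seed = 1, subject_ids = ids, by_subject = TRUE)
  per_subject <- tapply(s, ids, function(v) length(unique(v)))
  expect_true(all(per_subject == 1))
  expect_equal(sum(tapply(s, ids, `[`, 1) == "train"), 8)
})

test_that("feature encoding imputes medians and adds indicator columns", {
  df <- data.frame(a = c(1, NA, 3), b = c(4, 5, 6))
  enc <- encode_features(df, c("a", "b"))
  expect_equal(enc$x$a, c(1, 2, 3))
  expect_equal(enc$x$miss_a, c(0, 1, 0))
  expect_false("miss_b" %in% names(enc$x))
  # reapplication uses the learned medians
  enc2 <- encode_features(data.frame(a = NA_real_, b = 9), c("a", "b"),
                          encoder = enc$encoder)
  expect_equal(enc2$x$a, 2)
  expect_error(encode_features(df, c("a", "zz")), "zz")
})

test_that("impurity importances normalize to one and threshold correctly", {
  set.seed(10)
  n <- 200
  x <- data.frame(signal = rnorm(n), junk1 = rnorm(n), junk2 = rnorm(n))
  y <- 3 * x$signal + rnorm(n, 0, 0.1)
  sel <- select_features(x, y, threshold = 0.02, seed = 1)
  expect_equal(sum(sel$importance), 1, tolerance = 1e-9)
  expect_true("signal" %in% sel$selected)
  all_sel <- select_features(x, y, threshold = 0, seed = 1)
  expect_setequal(all_sel$selected, names(x))
  expect_error(select_features(x, rep(5, n), seed = 1), "zero variance")
  expect_error(select_features(x[1:20, ], y[1:20], seed = 1), "50")
})

test_that("selection recovers the planted SBP drivers", {
  cfg <- default_config(n_subjects = 20)
  cfg$protocol$obs_per_condition <- 3L
  cfg <- validate_config(cfg)
  hits <- 0L
  for (s in 1:10) {
    d <- simulate_feature_dataset(cfg, seed = s)
    enc <- encode_features(d)
    sel <- select_features(enc$x, d$sbp, seed = s, num_trees = 300)
    if (all(c("r_to_s2", "age") %in% sel$selected)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("ensembles are deterministic, serializable and sane on edge cases", {
  cfg <- tiny_pipeline_config()
  d <- simulate_feature_dataset(cfg, seed = 2)
  targets <- data.frame(sbp = d$sbp, dbp = d$dbp)
  m1 <- train_models(d, targets, cfg = cfg, seed = 3)
  m2 <- train_models(d, targets, cfg = cfg, seed = 3)
  p1 <- predict(m1$sbp, d)
  expect_identical(p1, predict(m2$sbp, d))
  expect_true(all(is.finite(p1)))
  expect_true(all(p1 >= min(d$sbp) - 5 & p1 <= max(d$sbp) + 5))

  # save -> load -> predict is bit-identical
  f <- withr::local_tempfile(fileext = ".rds")
  saveRDS(m1, f)
  expect_identical(predict(readRDS(f)$sbp, d), p1)

  # duplicate rows get identical estimates
  dup <- rbind(d[1, ], d[1, ])
  expect_equal(diff(predict(m1$sbp, dup)), 0)

  # missing selected feature is a named error
  expect_error(predict(m1$sbp, d[, setdiff(names(d), "r_to_s2")]), "r_to_s2")

  # constant target: predictions collapse to it
  const <- train_models(d, data.frame(sbp = rep(120, nrow(d)),
                                      dbp = rep(80, nrow(d))),
                        cfg = cfg, seed = 4)
  expect_equal(predict(const$sbp, d), rep(120, nrow(d)), tolerance = 1e-3)

  # NA in target refuses to train
  bad <- targets; bad$sbp[1] <- NA
  expect_error(train_models(d, bad, cfg = cfg, seed = 5), "NA in target")
})

test_that("signal model beats the demographics baseline under planted coupling", {
  cfg <- tiny_pipeline_config()
  wins <- 0L
  for (s in 1:3) {
    d <- simulate_feature_dataset(cfg, seed = s)
    split <- split_dataset(nrow(d), seed = s)
    tr <- d[split == "train", ]; te <- d[split == "test", ]
    m <- train_models(tr, data.frame(sbp = tr$sbp, dbp = tr$dbp),
                      cfg = cfg, seed = s)
    r_m <- rmse_error(predict(m$sbp, te), te$sbp)
    r_b <- rmse_error(predict(m$baseline_sbp, te), te$sbp)
    if (r_m < r_b) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})
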