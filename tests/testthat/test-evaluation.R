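test_that("MAD, MAPD and RMSE match hand-computed values", {
  p <- c(122, 116); y <- c(120, 120)
  expect_equal(mad_error(p, y), 3)                      # (2 + 4) / 2
  expect_equal(rmse_error(p, y), sqrt(10))              # sqrt((4 + 16) / 2)
  expect_equal(mapd_error(p, y), 2.5)                   # 100*(2/120 + 4/120)/2

  expect_equal(mad_error(y, y), 0)
  expect_equal(mapd_error(y, y), 0)
  expect_equal(rmse_error(y, y), 0)

  expect_equal(mad_error(118, 124), 6)                  # n = 1: MAD == RMSE
  expect_equal(rmse_error(118, 124), 6)

  expect_error(mad_error(numeric(0), numeric(0)), "empty")
  expect_error(mapd_error(1, 0), "zero")
  expect_error(rmse_error(c(1, NA), c(1, 2)), "NA")
})

test_that("RMSE dominates MAD on random pair sets", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    y <- runif(n, 60, 200)
    p <- y + rnorm(n, 0, runif(1, 0.1, 20))
    expect_gte(rmse_error(p, y) + 1e-12, mad_error(p, y))
  }
})

test_that("stratified report respects the weighted-mean identity", {
  pairs <- data.frame(
    p = c(124, 118, 130, 150, 160), y = c(120, 120, 128, 140, 150),
    target = "sbp",
    condition = c("static", "static", "static", "cold_walk", "cold_walk"),
    split = "test")
  rep <- stratified_report(pairs)
  m <- rep$metrics
  overall <- m[m$stratum == "overall", ]
  st <- m[m$stratum == "static", ]
  cw <- m[m$stratum == "cold_walk", ]
  expect_equal(overall$mad,
               (st$n * st$mad + cw$n * cw$mad) / (st$n + cw$n))
  expect_equal(overall$n, 5)

  # single-condition pair set: stratum equals overall
  one <- pairs[pairs$condition == "static", ]
  rep1 <- stratified_report(one)
  m1 <- rep1$metrics
  expect_equal(m1$mad[m1$stratum == "static"], m1$mad[m1$stratum == "overall"])

  # empty cell is n = 0 with absent metrics
  pairs2 <- pairs; pairs2$split <- c("test", "test", "test", "train", "train")
  m2 <- stratified_report(pairs2)$metrics
  cell <- m2[m2$stratum == "cold_walk" & m2$split == "test", ]
  expect_equal(cell$n, 0)
  expect_true(is.na(cell$mad))
})

test_that("Bland-Altman limits match the closed form for symmetric errors", {
  e <- 4
  y <- rep(c(120, 140), each = 50)
  p <- y + rep(c(e, -e), 50)
  ba <- bland_altman(p, y)
  expect_equal(ba$mean_diff, 0)
  sd_d <- sd(rep(c(e, -e), 50))
  expect_equal(ba$loa_upper, 1.96 * sd_d)
  expect_equal(ba$loa_lower, -1.96 * sd_d)
  expect_equal(ba$n, 100)
})

test_that("paired bootstrap comparison implements the superiority rule", {
  set.seed(5)
  y <- runif(300, 80, 180)
  e <- rnorm(300, 0, 5)
  p_model <- y + e

  # identical models: zero difference in every resample, p = 1
  cmp <- bootstrap_rmse_comparison(p_model, p_model, y, n_resamples = 2000,
                                   seed = 1)
  expect_equal(unname(cmp$diff_rmse["estimate"]), 0)
  expect_equal(cmp$p_value, 1)
  expect_false(cmp$superior)

  # baseline errors inflated by a constant on every pair: the paired
  # construction forces a negative difference in every resample
  p_base <- y + sign(e + 1e-9) * (abs(e) + 5)
  cmp <- bootstrap_rmse_comparison(p_model, p_base, y, n_resamples = 2000,
                                   seed = 2)
  expect_lt(cmp$diff_rmse[["ci_upper"]], 0)
  expect_true(cmp$superior)
  expect_equal(cmp$p_value, 1 / 2000)               # floored at 1/B

  # determinism and CI-contains-estimate invariants
  cmp2 <- bootstrap_rmse_comparison(p_model, p_base, y, n_resamples = 2000,
                                    seed = 2)
  expect_identical(unclass(cmp), unclass(cmp2))
  expect_true(cmp$model_rmse[["ci_lower"]] <= cmp$model_rmse[["estimate"]] &&
              cmp$model_rmse[["estimate"]] <= cmp$model_rmse[["ci_upper"]])
  expect_error(bootstrap_rmse_comparison(p_model, p_base[-1], y),
               "same observations")
})

test_that("bootstrap MAD interval behaves on degenerate and seeded input", {
  y <- rep(120, 30)
  p <- y + 3                                        # all errors identical
  ci <- bootstrap_mad_ci(p, y, n_iterations = 500, seed = 1)
  expect_equal(as.numeric(ci), c(3, 3))
  expect_equal(attr(ci, "estimate"), 3)

  set.seed(2)
  y <- runif(100, 80, 180); p <- y + rnorm(100, 0, 6)
  a <- bootstrap_mad_ci(p, y, seed = 42)
  b <- bootstrap_mad_ci(p, y, seed = 42)
  expect_identical(a, b)
  expect_true(a[["lower"]] <= attr(a, "estimate") &&
              attr(a, "estimate") <= a[["upper"]])
  expect_error(bootstrap_mad_ci(1:5, 2:6), "at least 10")
})
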