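test_that("cohort stratification matches target fractions with floor rounding", {
  co <- generate_cohort(120, seed = 1)
  expect_identical(as.integer(table(co$bp_class)), c(24L, 44L, 31L, 21L))
  expect_equal(nrow(co), 120)

  co4 <- generate_cohort(4, c(normal = .25, prehypertension = .25,
                              stage1 = .25, stage2 = .25), seed = 3)
  expect_identical(as.integer(table(co4$bp_class)), rep(1L, 4))
})

test_that("cohort generation is deterministic and respects invariants", {
  a <- generate_cohort(40, seed = 9)
  b <- generate_cohort(40, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(40, seed = 10)))

  expect_true(all(a$age >= 18 & a$age <= 83))
  expect_true(all(a$height > 0 & a$weight > 0))
  expect_true(all(c("male", "female") %in% a$sex))
  expect_true(all(a$entry_sbp - a$entry_dbp >= 15))
  expect_identical(classify_jnc7(a$entry_sbp, a$entry_dbp), a$bp_class)
  expect_error(generate_cohort(3, seed = 1), ">= 4")
  expect_error(generate_cohort(10, c(normal = 2, prehypertension = 1,
                                     stage1 = 1, stage2 = 1), seed = 1),
               "sum to 1")
})

test_that("condition offsets modulate BP in the protocol's directions", {
  cfg <- default_config()
  subj <- c(entry_sbp = 130, entry_dbp = 85)
  set.seed(1)
  draws <- lapply(c("warm_rest", "static", "cold_walk"), function(cd) {
    simulate_condition_bp(subj, cd, n = 1000, cfg = cfg,
                          subject_effect = c(sbp = 0, dbp = 0))
  })
  m <- vapply(draws, function(d) mean(d$sbp), numeric(1))
  expect_lt(m[1], 130)          # warm stimulus lowers
  expect_gt(m[3], 130)          # cold pressor + walk raises
  expect_true(m[1] < m[2] && m[2] < m[3])
  expect_true(all(vapply(draws, function(d) all(d$sbp - d$dbp >= 15), logical(1))))
  expect_error(simulate_condition_bp(subj, "jogging"), "unknown condition")
})

test_that("modulation means match configured offsets within Monte-Carlo error", {
  cfg <- default_config()
  subj <- c(entry_sbp = 130, entry_dbp = 85)
  n <- 1000
  se <- cfg$bp_modulation$observation_sd / sqrt(n)
  for (cd in protocol_conditions()) {
    set.seed(42)
    d <- simulate_condition_bp(subj, cd, n = n, cfg = cfg,
                               subject_effect = c(sbp = 0, dbp = 0))
    expect_lt(abs(mean(d$sbp) - (130 + cfg$bp_modulation$sbp_offset[[cd]])), 3 * se)
  }
})

test_that("observer readings land on the 2-mmHg grid with half-to-even ties", {
  cfg <- default_config()
  cfg$observers$noise_sd_mmhg <- 0
  ob <- simulate_observers(120, 80, cfg, cuff = FALSE)
  expect_equal(unlist(ob), c(obs1_sbp = 120, obs1_dbp = 80,
                             obs2_sbp = 120, obs2_dbp = 80))
  # 121 is a tie between 120 and 122; banker's rounding picks the even
  # multiple of the grid step, 60*2 = 120
  ob <- simulate_observers(121, 79, cfg, cuff = FALSE)
  expect_equal(ob$obs1_sbp, 120)
  set.seed(2)
  ob <- simulate_observers(rep(124, 500), rep(80, 500), default_config())
  expect_true(all(ob$obs1_sbp %% 2 == 0))
})

test_that("observer disagreement rate matches the rounded-normal oracle", {
  # oracle: P(round2(t+e1) - round2(t+e2) > 4) by enumerating the exact
  # distribution of each rounded reading over the 2-mmHg grid
  sd <- default_config()$observers$noise_sd_mmhg
  t <- 124
  grid <- seq(t - 20, t + 20, by = 2)
  p_read <- pnorm(grid + 1, t, sd) - pnorm(grid - 1, t, sd)
  p_read <- p_read / sum(p_read)
  p_disagree <- 0
  for (i in seq_along(grid)) {
    far <- abs(grid - grid[i]) > 4
    p_disagree <- p_disagree + p_read[i] * sum(p_read[far])
  }
  n <- 10000
  set.seed(11)
  ob <- simulate_observers(rep(t, n), rep(80, n), default_config(), cuff = FALSE)
  frac <- mean(abs(ob$obs1_sbp - ob$obs2_sbp) > 4)
  se <- sqrt(p_disagree * (1 - p_disagree) / n)
  expect_lt(abs(frac - p_disagree), 3 * se)
})

test_that("planted signal-BP coupling has the configured sign", {
  cfg <- noise_free_config()
  sched <- session_schedule(cfg)
  co <- generate_cohort(4, c(normal = .5, prehypertension = 0,
                             stage1 = 0, stage2 = .5), seed = 4)
  lo <- co[which(co$entry_sbp == min(co$entry_sbp))[1], ]
  hi <- co[which(co$entry_sbp == max(co$entry_sbp))[1], ]
  set.seed(1); gt_lo <- observation_ground_truth(lo, sched, cfg)
  set.seed(1); gt_hi <- observation_ground_truth(hi, sched, cfg)
  expect_lt(mean(gt_hi$r_to_s2), mean(gt_lo$r_to_s2))
  expect_true(all(gt_lo$r_to_s1 < gt_lo$r_to_s2))
  expect_true(all(gt_lo$r_to_s2 < 60 / gt_lo$heart_rate))
})

test_that("with coupling disabled signal features are independent of BP", {
  # permutation correlation test at alpha = 0.01 across 50 generator runs:
  # the false-positive count should be binomial(50, 0.01)
  cfg <- default_config(n_subjects = 8)
  cfg$coupling$enabled <- FALSE
  cfg <- validate_config(cfg)
  perm_p <- function(x, y, n_perm = 400, seed) {
    set.seed(seed)
    r0 <- abs(cor(x, y))
    r <- replicate(n_perm, abs(cor(x, sample(y))))
    (1 + sum(r >= r0)) / (n_perm + 1)
  }
  hits <- 0L
  for (s in 1:50) {
    d <- simulate_feature_dataset(cfg, seed = s)
    if (perm_p(d$r_to_s2, d$true_sbp, seed = s) < 0.01) hits <- hits + 1L
  }
  expect_lte(hits, 4L)   # P(>4 | Binom(50, .01)) < 2e-4
})

test_that("feature-level dataset is deterministic and class-complete", {
  cfg <- tiny_pipeline_config()
  a <- simulate_feature_dataset(cfg, seed = 3)
  b <- simulate_feature_dataset(cfg, seed = 3)
  expect_identical(a, b)
  expect_true(all(feature_registry() %in% names(a)))
  expect_true(all(protocol_conditions() %in% unique(a$condition)))
  expect_true(all(a$sbp > a$dbp))
})
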