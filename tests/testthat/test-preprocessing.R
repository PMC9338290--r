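# brute-force oracle: test every integer start offset, latest wins
oracle_window <- function(comp, t_obs, lookback = 300, W = 60) {
  s_min <- max(0, ceiling(t_obs - lookback))
  s_max <- min(floor(t_obs) - W, length(comp) - W)
  best <- NA
  s <- s_min
  while (s <= s_max) {
    if (all(comp[(s + 1):(s + W)])) best <- s
    s <- s + 1
  }
  best
}

test_that("clean synthetic recording is fully acceptable", {
  fx <- noise_free_session()
  mask <- assess_quality(fx$ses$recording, fx$cfg)
  expect_equal(mean(mask$composite), 1)
})

test_that("injected movement epochs are flagged", {
  cfg <- noise_free_config()
  cfg$signals$movement_epochs_per_session <- 1L
  co <- generate_cohort(4, seed = 5)
  ses <- synthesize_recording(co[2, ], cfg, seed = 12)
  mask <- assess_quality(ses$recording, cfg)
  ep <- ses$movement_epochs
  secs <- seq(ceiling(ep$start_s[1]), floor(ep$end_s[1]) - 1)
  expect_gte(mean(!mask$composite[secs + 1]), 0.95)
})

test_that("degenerate channels are rejected wholesale", {
  rec <- new_recording(
    list(ecg1 = list(samples = numeric(30 * 500), fs = 500, units = "mV"),
         pcg = list(samples = rnorm(30 * 500), fs = 500, units = "a.u."),
         imp1 = list(samples = 25 + sin(seq_len(30 * 50) / 8), fs = 50,
                     units = "ohm")),
    subject_id = "S1")
  mask <- assess_quality(rec, default_config())
  expect_equal(mean(mask$per_channel[, "ecg1"]), 0)   # flatline
  expect_equal(mean(mask$composite), 0)
  short <- new_recording(list(ecg1 = list(samples = rnorm(100), fs = 500,
                                          units = "mV")), "S1")
  expect_error(assess_quality(short, default_config()), "shorter than 1 s")
})

test_that("window association returns the latest acceptable window", {
  cfg <- default_config()
  comp <- rep(TRUE, 400)
  w <- associate_window(comp, 350, cfg)
  expect_equal(c(w$window_start, w$window_end), c(290, 350))

  # only the very start of the lookback is clean
  comp <- rep(FALSE, 400)
  comp[(50:109) + 1] <- TRUE   # seconds 50..109
  w <- associate_window(comp, 350, cfg)
  expect_equal(c(w$window_start, w$window_end), c(50, 110))

  # no clean run anywhere
  comp <- rep(c(TRUE, FALSE), 200)
  w <- associate_window(comp, 350, cfg)
  expect_false(w$accepted)
  expect_equal(w$reason, "no_acceptable_window")
})

test_that("truncated lookback and centered mode behave as documented", {
  cfg <- default_config()
  comp <- rep(TRUE, 400)
  w <- associate_window(comp, 90, cfg)    # only 90 s of data before obs
  expect_true(w$accepted)
  expect_true(w$truncated_lookback)
  expect_equal(c(w$window_start, w$window_end), c(30, 90))

  cfg$window$mode <- "centered"
  w <- associate_window(comp, 200, cfg)
  expect_equal(c(w$window_start, w$window_end), c(170, 230))
})

test_that("window association equals the brute-force oracle on random masks", {
  set.seed(99)
  cfg <- default_config()
  for (i in 1:200) {
    comp <- runif(400) > runif(1, 0.02, 0.5)
    t_obs <- sample(100:399, 1) + round(runif(1), 2)
    w <- associate_window(comp, t_obs, cfg)
    o <- oracle_window(comp, t_obs)
    if (is.na(o)) {
      expect_false(w$accepted)
    } else {
      expect_equal(w$window_start, o)
      expect_equal(w$window_end - w$window_start, 60)
      expect_lte(w$window_end, t_obs)
      expect_gte(w$window_start, t_obs - 300)
      expect_true(all(comp[(o + 1):(o + 60)]))
    }
  }
})

test_that("adding bad seconds never creates a window where none existed", {
  set.seed(7)
  cfg <- default_config()
  for (i in 1:50) {
    comp <- runif(400) > 0.3
    t_obs <- 390
    before <- associate_window(comp, t_obs, cfg)
    comp2 <- comp
    comp2[sample(400, 20)] <- FALSE
    after <- associate_window(comp2, t_obs, cfg)
    if (!before$accepted) expect_false(after$accepted)
  }
})
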