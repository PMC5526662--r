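test_that("every trial has 5-9 taps before its stop cue", {
  cfg <- tiny_sim(seed = 2, n_stop_trials = 40)
  beh <- simulate_behavior(cfg)
  ev <- beh$events
  for (tr in unique(ev$trial_idx)) {
    cue <- min(ev$time[ev$trial_idx == tr & ev$event_type == "stop_cue"])
    n_pre <- sum(ev$trial_idx == tr & ev$event_type == "tap_onset" &
                   ev$time < cue)
    expect_gte(n_pre, 5); expect_lte(n_pre, 9)
  }
  expect_s3_class(validate_event_table(ev), "event_table")
})

test_that("zero jitter puts taps on the metronome grid and the cue at +707 ms", {
  cfg <- tiny_sim(seed = 3, n_stop_trials = 10, tap_jitter_sd = 0,
                  tap_mean_offset = 0)
  beh <- simulate_behavior(cfg)
  ev <- beh$events
  taps <- ev[ev$event_type == "tap_onset" & !is.na(ev$tap_idx), ]
  metro <- ev[ev$event_type == "metronome", ]
  reg <- merge(taps, metro, by = c("trial_idx", "tap_idx"))
  expect_equal(reg$time.x, reg$time.y, tolerance = 1e-9)
  expect_equal(beh$trials$stop_delay, rep(707, 10), tolerance = 1e-9)
})

test_that("empirical success rate sits in the 99% binomial interval", {
  cfg <- tiny_sim(seed = 9, n_stop_trials = 2000)
  beh <- simulate_behavior(cfg)
  rate <- mean(beh$trials$outcome != "failed")
  band <- qnorm(0.995) * sqrt(0.55 * 0.45 / 2000)
  expect_gt(rate, 0.55 - band)
  expect_lt(rate, 0.55 + band)
  # behavioral marginals: stop delay and tap jitter match configuration
  expect_equal(mean(beh$trials$stop_delay), 707, tolerance = 1e-6)
  offs <- beh$truth$tap_sound_offset
  expect_equal(mean(offs), -30, tolerance = 3 * 40 / sqrt(2000))
  expect_equal(sd(offs), 40, tolerance = 3)
})

test_that("signal synthesis is a deterministic function of the config", {
  sub <- tiny_subject()
  rec2 <- simulate_signals(sub$cfg, sub$events, sub$truth)
  expect_identical(sub$recording$data, rec2$data)
})

test_that("outcome classes shape the goniometer descent", {
  sub <- tiny_subject()
  rec <- sub$recording; tr <- sub$truth
  gon <- channel_data(rec, "goniometer")
  fs <- rec$sample_rate
  for (i in seq_len(nrow(tr))) {
    post <- gon[floor(tr$stop_time[i] * fs):floor((tr$stop_time[i] + 0.9) * fs)]
    pre_apex <- max(gon[floor((tr$stop_time[i] - 0.9) * fs):
                          floor((tr$stop_time[i] + 0.1) * fs)])
    drop_frac <- (pre_apex - min(post)) / pre_apex
    expect_equal(100 * drop_frac, tr$movement_extent[i], tolerance = 8)
  }
})

test_that("pressure pulses appear after the cue only in failed trials", {
  sub <- tiny_subject()
  rec <- sub$recording; tr <- sub$truth
  pres <- channel_data(rec, "pressure")
  taps <- detect_taps(pres, rec$sample_rate)
  for (i in seq_len(nrow(tr))) {
    post_hit <- any(taps$onset > tr$stop_time[i] &
                      taps$onset < tr$stop_time[i] + 0.9)
    expect_identical(post_hit, tr$outcome[i] == "failed")
  }
})

test_that("with bursts disabled the post-cue STN gamma stays at baseline", {
  cfg <- control_config(tiny_sim(seed = 21, n_stop_trials = 8))
  beh <- simulate_behavior(cfg)
  rec <- simulate_signals(cfg, beh$events, beh$truth)
  x <- resample_signal(channel_data(rec, "STN_contra"), 2048, 1000)
  p <- smooth_power(band_power(x, 1000, c(60, 90)), 1000)
  times <- (seq_along(p) - 1) / 200
  post <- pre <- numeric(0)
  for (st in beh$truth$stop_time) {
    post <- c(post, p[times >= st & times < st + 0.2])
    pre <- c(pre, p[times >= st - 0.3 & times < st - 0.1])
  }
  expect_lt(abs(mean(post) - mean(pre)) / mean(pre), 0.25)
})

test_that("EOG regression tracks the injected blink leakage", {
  # with blinks, the per-channel scale approaches the configured leak;
  # without blinks the EOG is a pure noise floor and only chance
  # correlation of slow components remains (compared after DC removal,
  # as in the preprocessing chain)
  run <- function(rate) {
    cfg <- tiny_sim(seed = 22, n_stop_trials = 10, blink_rate = rate)
    beh <- simulate_behavior(cfg)
    rec <- simulate_signals(cfg, beh$events, beh$truth)
    pp <- preprocess_recording(rec,
                               preproc_config(reference = "common_average"))
    list(rec = rec, scales = pp$eog_scales)
  }
  with_blinks <- run(12)
  no_blinks <- run(0)
  # blink bumps (amplitude 30) present only in the first case
  expect_gt(max(abs(channel_data(with_blinks$rec, "EOG"))), 10)
  expect_lt(max(abs(channel_data(no_blinks$rec, "EOG"))), 10)
  # common-average referencing reduces the effective Fz leak from 0.35
  # to 0.35 minus the mean leak (~0.21), which the regression recovers
  expect_equal(abs(with_blinks$scales[["Fz"]]), 0.207, tolerance = 0.05)
  expect_gt(abs(with_blinks$scales[["Fz"]]),
            3 * abs(no_blinks$scales[["Fz"]]))
  expect_lt(abs(no_blinks$scales[["Fz"]]), 0.1)
})

test_that("datasets derive distinct per-subject seeds deterministically", {
  cfg <- tiny_sim(seed = 30, n_subjects = 3, n_stop_trials = 2)
  ds <- simulate_dataset(cfg)
  expect_length(ds, 3)
  seeds <- vapply(ds, function(s) s$params$seed, numeric(1))
  expect_length(unique(seeds), 3)
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds[[1]]$recording$data, ds2[[1]]$recording$data)
  cfg2 <- cfg; cfg2$seed <- 31
  ds3 <- simulate_dataset(cfg2)
  expect_false(identical(ds[[1]]$recording$data, ds3[[1]]$recording$data))
  hands <- vapply(ds, function(s) s$params$tapping_hand, character(1))
  expect_identical(hands, c("right", "right", "right"))
})

test_that("zero between-subject SD replicates effect parameters", {
  cfg <- tiny_sim(seed = 33, n_subjects = 3, n_stop_trials = 2,
                  between_subject = list(amp_sd = 0, latency_sd = 0,
                                         delay_sd = 0))
  ds <- simulate_dataset(cfg)
  expect_equal(vapply(ds, function(s) s$params$amp_factor, numeric(1)),
               rep(1, 3))
  expect_equal(vapply(ds, function(s) s$params$stop_delay, numeric(1)),
               rep(707, 3))
})
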