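test_that("tap detection finds constructed pulses to one sample", {
  fs <- 1000
  pres <- numeric(5000)
  onsets <- c(1.0, 2.2, 3.4)
  for (o in onsets) pres[(o * fs):(o * fs + 119)] <- 1  # 120 ms contact
  taps <- detect_taps(pres, fs)
  expect_equal(nrow(taps), 3)
  expect_equal(taps$onset, onsets - 1 / fs, tolerance = 1.5 / fs)
  expect_equal(taps$down_time, rep(120, 3), tolerance = 1.5)
  expect_equal(nrow(detect_taps(numeric(1000), fs)), 0)
})

test_that("movement extent reproduces the defining examples", {
  fs <- 1000
  t <- (0:2999) / fs
  # flexion cycle: rest, rise to 6 by t=1, descend after the cue at t=1.2
  make_trace <- function(down_amount) {
    g <- numeric(3000)
    g[t >= 0.5 & t < 1.0] <- 6 * (t[t >= 0.5 & t < 1.0] - 0.5) / 0.5
    g[t >= 1.0] <- 6
    desc <- t >= 1.3 & t < 1.5
    g[desc] <- 6 - down_amount * (t[desc] - 1.3) / 0.2
    g[t >= 1.5] <- 6 - down_amount
    g
  }
  expect_equal(movement_extent(make_trace(6), fs, 1.2)$extent, 100,
               tolerance = 0.5)
  expect_equal(movement_extent(make_trace(3), fs, 1.2)$extent, 50,
               tolerance = 0.5)  # up 6 units, down 3 units
  expect_equal(movement_extent(make_trace(0), fs, 1.2)$extent, 0,
               tolerance = 0.5)  # no downward movement: full stop
  # degenerate: no preceding upward movement
  flat <- movement_extent(numeric(3000), fs, 1.2)
  expect_true(flat$flagged)
  expect_true(is.na(flat$extent))
})

test_that("outcome classification partitions all cases", {
  expect_identical(classify_outcome(7, FALSE), "full")
  expect_identical(classify_outcome(55, FALSE), "intermediate")
  expect_identical(classify_outcome(98, TRUE), "failed")
  # touched dominates regardless of extent; NA extent stays total
  expect_identical(classify_outcome(3, TRUE), "failed")
  expect_identical(classify_outcome(NA, FALSE), "intermediate")
  set.seed(1)
  for (i in 1:50) {
    out <- classify_outcome(runif(1, 0, 120), runif(1) < 0.5)
    expect_true(out %in% c("full", "intermediate", "failed"))
  }
})

test_that("arrhythmic taps are flagged and their trials excluded", {
  ev <- event_table(
    event_type = c("metronome", "tap_onset", "metronome", "tap_onset",
                   "stop_cue",
                   "metronome", "tap_onset", "metronome", "tap_onset",
                   "stop_cue"),
    time = c(0.9, 0.9 + 0.310, 1.8, 1.8 - 0.290, 2.6,
             10.0, 10.0, 10.9, 10.9, 11.7),
    trial_idx = c(rep(0, 5), rep(1, 5)),
    tap_idx = c(1, 1, 2, 2, NA, 1, 1, 2, 2, NA))
  res <- exclude_arrhythmic(ev)
  flags <- res$events$tap_flagged[res$events$event_type == "tap_onset"]
  expect_identical(flags, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(res$excluded_trials, 0L)  # flagged tap precedes cue
})

test_that("tap metrics report the last regular tap's covariates", {
  sub <- tiny_subject()
  tm <- tap_metrics(sub$events, sub$recording)
  truth <- sub$truth
  expect_equal(nrow(tm), nrow(truth))
  expect_equal(tm$tapNr, truth$n_taps)
  expect_equal(tm$soundOffset, truth$tap_sound_offset, tolerance = 1)
  expect_true(all(tm$downTime > 50 & tm$downTime < 250, na.rm = TRUE))
  expect_true(all(tm$maxPres > 0.5, na.rm = TRUE))
  expect_true(all(tm$upMvmt > 0.5, na.rm = TRUE))
  expect_true(all(tm$peakVelUp > 0, na.rm = TRUE))
})

test_that("goniometer velocity of a pure ramp equals its slope", {
  fs <- 500
  ramp <- recording(rbind(seq(0, 10, length.out = 2501)),
                    "goniometer", "goniometer", fs)
  # slope = 10 units over 5 s = 2 units/s; inject as only channel
  gon <- channel_data(ramp, "goniometer")
  vel <- c(0, (gon[-c(1, 2)] - gon[-c(length(gon) - 1, length(gon))]) /
             (2 / fs), 0)
  expect_equal(max(vel), 2, tolerance = 0.01)
})

test_that("recovered movement extent matches the generator's latent value", {
  sub <- tiny_subject()
  tt <- build_trial_table(sub$recording, sub$events,
                          interval = sub$cfg$metronome_interval / 1000)
  truth <- sub$truth
  m <- match(truth$trial_idx, tt$trial_idx)
  ok <- !tt$excluded[m]
  expect_gt(mean(ok), 0.8)
  expect_equal(tt$movement_extent[m][ok], truth$movement_extent[ok],
               tolerance = 4)
  # outcome classes agree except near the 10% boundary
  agree <- tt$outcome[m][ok] == truth$outcome[ok]
  near <- abs(truth$movement_extent[ok] - 10) < 4
  expect_true(all(agree | near))
})
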