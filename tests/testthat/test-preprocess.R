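test_that("DC removal: zero in, zero out; step decays with RC = 2 s", {
  fs <- 500
  expect_equal(remove_dc(numeric(1000), fs), numeric(1000))
  # constant input: output decays toward 0 as c * exp(-t / RC)
  x <- rep(2, 6 * fs)
  y <- remove_dc(x, fs, time_constant = 2)
  t_check <- c(0.5, 1, 2, 3)
  for (tc in t_check)
    expect_equal(y[round(tc * fs) + 1], 2 * exp(-tc / 2),
                 tolerance = 0.01 * 2 * exp(-tc / 2))
})

test_that("DC removal leaves a 10 Hz oscillation essentially untouched", {
  fs <- 1000; t <- (0:9999) / fs
  x <- sin(2 * pi * 10 * t)
  y <- remove_dc(x, fs, 2)
  expect_equal(max(abs(y[5000:9000])), 1, tolerance = 0.01)
})

test_that("common-average reference zeroes the per-sample EEG mean", {
  rec <- toy_recording(n_chan = 4)
  out <- rereference(rec, "common_average")
  expect_equal(max(abs(colSums(out$data))), 0, tolerance = 1e-10)
  expect_identical(out$reference, "common_average")
  # identical EEG channels: all zeros after common average
  rec2 <- recording(matrix(rep(rnorm(100), each = 3), 3),
                    c("a", "b", "c"), rep("eeg", 3), 100)
  expect_equal(max(abs(rereference(rec2, "common_average")$data)), 0)
})

test_that("linked-earlobe reference subtracts the earlobe mean", {
  dat <- rbind(rnorm(200), rnorm(200), 0, 0)
  rec <- recording(dat, c("Cz", "Pz", "A1", "A2"),
                   c("eeg", "eeg", "earlobe", "earlobe"), 100)
  out <- rereference(rec, "linked_earlobes")
  expect_equal(out$data[1:2, ], dat[1:2, ])  # zero earlobes: unchanged
  rec_no_ears <- toy_recording()
  expect_error(rereference(rec_no_ears, "linked_earlobes"),
               "earlobe")
})

test_that("bipolar derivation cancels common-mode signal", {
  common <- sin(seq(0, 10, length.out = 500))
  s <- rnorm(500)
  dat <- rbind(common + s, common, common + 2 * s)
  rec <- recording(dat, c("c1", "c2", "c3"), rep("lfp_mono", 3), 200)
  out <- derive_bipolars(rec, list(c("c1", "c2"), c("c2", "c2")))
  expect_equal(channel_data(out, "c1-c2"), s)        # common mode gone
  expect_equal(channel_data(out, "c2-c2"), rep(0, 500))
  expect_identical(out$channels$kind[4:5], rep("lfp_bipolar", 2))
  expect_error(derive_bipolars(rec, list(c("c1", "nope"))), "unknown")
})

test_that("EOG regression recovers a constructed leakage scale", {
  set.seed(3)
  fs <- 500; n <- 10000
  eog <- one_over_f_noise(n, fs, 1)
  cfg <- preproc_config()
  bf <- signal::butter(cfg$filter_order, 40 / (fs / 2), "low")
  e <- signal::filtfilt(bf, eog)
  brain <- sin(2 * pi * 23 * (0:(n - 1)) / fs)  # narrow-band, ~orthogonal
  brain <- brain - e * sum(brain * e) / sum(e * e)
  eeg <- brain + 0.5 * e
  fit <- remove_eog(eeg, eog, fs, cfg)
  expect_equal(fit$scale, 0.5, tolerance = 1e-6)
  expect_equal(fit$cleaned, brain, tolerance = 1e-6)
})

test_that("EOG regression handles degenerate and null cases", {
  set.seed(4)
  eeg <- rnorm(5000)
  expect_warning(fit <- remove_eog(eeg, numeric(5000), 500), "zero")
  expect_identical(fit$scale, 0)
  expect_identical(fit$cleaned, eeg)
  # independent noise: |scale| below 3 standard errors of the slope
  eog <- rnorm(5000)
  fit2 <- remove_eog(eeg, eog, 500)
  bf <- signal::butter(6, 40 / 250, "low")
  e <- signal::filtfilt(bf, eog)
  se <- sd(eeg) / sqrt(sum(e^2))
  expect_lt(abs(fit2$scale), 3 * se)
  # least-squares optimality: residual variance never increases
  expect_lte(var(fit2$cleaned), var(eeg) + 1e-12)
})

test_that("full preprocessing chain is deterministic and EEG-optional", {
  sub <- tiny_subject()
  short <- sub$recording
  keep <- 1:(60 * short$sample_rate)
  short$data <- short$data[, keep]
  a <- preprocess_recording(short)
  b <- preprocess_recording(short)
  expect_identical(a$rec$data, b$rec$data)
  expect_equal(a$rec$sample_rate, 1000)
  expect_named(a$eog_scales, channels_of_kind(short, "eeg"))
  # recording without EEG: chain skips EEG stages instead of failing
  no_eeg <- short
  drop <- no_eeg$channels$kind %in% c("eeg", "eog")
  no_eeg$channels <- no_eeg$channels[!drop, ]
  no_eeg$data <- no_eeg$data[!drop, ]
  out <- preprocess_recording(no_eeg)
  expect_null(out$eog_scales)
  expect_equal(out$rec$sample_rate, 1000)
})
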