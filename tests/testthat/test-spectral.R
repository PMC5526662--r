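test_that("band power of a centered tone equals its squared amplitude", {
  fs <- 1000; t <- (0:19999) / fs
  for (A in c(1, 2.5)) {
    x <- A * sin(2 * pi * 70 * t)
    p <- band_power(x, fs, c(65, 75))
    expect_equal(mean(p[5000:15000]), A^2, tolerance = 0.02 * A^2)
  }
  expect_equal(band_power(numeric(1000), fs, c(65, 75)), numeric(1000))
  expect_error(band_power(rnorm(100), fs, c(480, 520)), "invalid")
})

test_that("disjoint bands of white noise give near-uncorrelated power", {
  set.seed(8)
  x <- rnorm(40000)
  p1 <- band_power(x, 1000, c(10, 20))
  p2 <- band_power(x, 1000, c(60, 90))
  mid <- 5000:35000
  expect_lt(abs(cor(p1[mid], p2[mid])), 0.1)
})

test_that("band-limited input keeps >= 95% of its variance in its band", {
  set.seed(9)
  fs <- 1000
  x <- signal::filtfilt(signal::butter(4, c(62, 72) / (fs / 2)),
                        rnorm(40000))
  p <- band_power(x, fs, c(60, 74))
  mid <- 5000:35000
  expect_gt(mean(p[mid]) / (2 * var(x[mid])), 0.95)
})

test_that("power smoothing averages and decimates as specified", {
  expect_equal(smooth_power(rep(4, 2000), 1000), rep(4, 400))
  x <- numeric(1000); x[500] <- 1
  y <- smooth_power(x, 1000, window_ms = 100, target_rate = 1000)
  expect_equal(sum(y > 1e-12), 100)
  expect_equal(max(y), 1 / 100)
  expect_length(smooth_power(rnorm(1000), 1000), 200)
})

test_that("epoching aligns and drops out-of-range trials", {
  fs <- 200
  vals <- matrix(rep(seq_len(2000), each = 2), nrow = 2, byrow = FALSE)
  tf <- tf_map(vals, c(10, 20), (0:1999) / fs)
  expect_message(epoch_tf(tf, c(2.0, 5.0, 9.99), c(-0.5, 0.5)),
                 "dropped")
  ep <- suppressMessages(epoch_tf(tf, c(2.0, 5.0, 9.99), c(-0.5, 0.5)))
  expect_equal(dim(ep), c(2, 2, 200))
  expect_identical(attr(ep, "kept"), 1:2)
  # the sample at relative time 0 equals the map value at the alignment
  i0 <- which(abs(attr(ep, "times")) < 1e-9)
  expect_equal(ep[1, 1, i0], vals[1, 2.0 * fs + 1])
  expect_equal(ep[2, 1, i0], vals[1, 5.0 * fs + 1])
})

test_that("virtual-stop alignment lands one tap earlier plus the delay", {
  # taps at 0 and 0.9 s, delay 707 ms: the virtual cue replays the delay
  # from the previous tap, i.e. -0.9 + 0.707 s relative to the last tap
  # and exactly one tapping interval before the true cue
  taps <- c(0, 0.9); delay <- 0.707
  cue <- taps[2] + delay
  virt <- taps[1] + delay
  expect_equal(virt - taps[2], -0.9 + 0.707, tolerance = 1e-12)
  expect_equal(virt - cue, -0.9, tolerance = 1e-12)
})

test_that("regular-tap normalization is an exact percent change", {
  ep <- array(2, c(3, 2, 4))
  base <- array(1, c(5, 2, 4))
  out <- normalize_to_regular_taps(ep, base)
  expect_equal(as.vector(out), rep(100, 24))
  expect_equal(as.vector(normalize_to_regular_taps(base[1:2, , ], base)),
               rep(0, 16))
  # inflating one baseline epoch x10 shifts the baseline accordingly
  base2 <- base
  base2[1, , ] <- 10
  expected_base <- apply(base2, 2, mean)
  out2 <- normalize_to_regular_taps(ep, base2)
  expect_equal(out2[1, 1, 1], 100 * (2 / expected_base[1] - 1))
  expect_error(normalize_to_regular_taps(ep, array(0, c(2, 2, 4))),
               "baseline")
})

test_that("normalized regular-tap epochs average to ~0% change", {
  sub <- tiny_subject()
  pp <- preprocess_recording(sub$recording)
  x <- channel_data(pp$rec, "STN_contra")
  fb <- filterbank_spec()
  fb$bands <- fb$bands[fb$bands$center %in% c(65, 75, 85), ]
  tf <- tf_power(x, 1000, fb)
  ev <- sub$events
  base_taps <- c()
  for (tr in unique(ev$trial_idx)) {
    taps <- ev$time[ev$trial_idx == tr & ev$event_type == "tap_onset" &
                      !is.na(ev$tap_idx)]
    cue <- min(ev$time[ev$trial_idx == tr & ev$event_type == "stop_cue"])
    reg <- sort(taps[taps < cue])
    if (length(reg) >= 3) base_taps <- c(base_taps, reg[2:(length(reg) - 1)])
  }
  base_ep <- epoch_tf(tf, base_taps, c(-0.45, 0.45), pp$flagged_edge_s)
  norm <- normalize_to_regular_taps(base_ep, base_ep)
  expect_lt(abs(mean(norm)), 1e-9)  # self-consistency by construction
})

test_that("bipolar selection maximizes the gamma modulation index", {
  # analytic index: time course m + (r/2) cos has index r/m
  m <- 4; r <- 2
  fs <- 1000
  tc <- m + (r / 2) * cos(2 * pi * (0:1799) / 1800)
  expect_equal((max(tc) - min(tc)) / mean(tc), r / m, tolerance = 1e-3)
  # generator-style check: tap-locked 75 Hz modulation on pair 2 only
  set.seed(14)
  hits <- 0
  for (rep in 1:5) {
    n <- 30000; t <- (0:(n - 1)) / fs
    taps <- c(3, 3.9, 4.8, 5.7, 6.6)
    env <- rep(0, n)
    for (tp in taps) env <- pmax(env, exp(-((t - tp) / 0.1)^2))
    carrier <- sin(2 * pi * 75 * t)
    cands <- list(flat1 = rnorm(n), mod = rnorm(n) + 3 * env * carrier,
                  flat2 = rnorm(n))
    sel <- select_bipolar(cands, fs, taps, 0.9)
    if (sel$selected == "mod") hits <- hits + 1
  }
  expect_gte(hits, 5 * 0.95 - 1)  # >= 95% of seeded runs at tiny scale
  expect_error(select_bipolar(list(), fs, taps), "candidate")
  expect_error(select_bipolar(list(a = rnorm(100)), fs, 1), "two taps")
})

test_that("flat power gives a zero modulation index", {
  fs <- 1000
  x <- sin(2 * pi * 75 * (0:19999) / fs)  # constant-envelope tone
  sel <- select_bipolar(list(a = x), fs, c(5, 6, 7), 0.9)
  expect_lt(sel$index[["a"]], 0.05)
})

test_that("band time courses average the right frequency rows", {
  vals <- rbind(rep(1, 5), rep(3, 5), rep(10, 5))
  tf <- tf_map(vals, c(60, 70, 95), (0:4) / 200)
  expect_equal(band_timecourse(tf, c(65, 75)), rep(3, 5))  # single bin
  expect_equal(band_timecourse(tf, c(55, 75)), rep(2, 5))  # (1+3)/2
  expect_error(band_timecourse(tf, c(120, 130)), "overlap")
  u <- tf_map(matrix(7, 3, 5), c(60, 70, 95), (0:4) / 200)
  expect_equal(band_timecourse(u, c(50, 100)), rep(7, 5))
})

test_that("peak latency: argmax with earliest-tie rule", {
  times <- seq(-0.2, 0.4, by = 0.005)
  bump <- exp(-((times - 0.106) / 0.03)^2)
  expect_equal(peak_latency(bump, times, c(0, 0.3)), 106, tolerance = 5)
  rising <- seq_along(times) / length(times)
  expect_equal(peak_latency(rising, times, c(0, 0.156)),
               max(times[times >= 0 & times < 0.156]) * 1000)
  flat <- rep(1, length(times))
  expect_equal(peak_latency(flat, times, c(0, 0.156)), 0)  # tie: earliest
  expect_true(is.na(peak_latency(rep(NA_real_, length(times)), times,
                                 c(0, 0.156))))
})
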