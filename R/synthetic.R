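#' Simulation configuration
#'
#' Ground-truth generator settings for the stop-signal tapping paradigm.
#' Defaults encode the study conditions: isochronous 900 ms metronome,
#' 5-9 anticipatory taps per trial, a stop cue ~707 ms after the last
#' registered tap, ~55% successful stopping, an outcome-coupled
#' subthalamic gamma burst around 70 Hz that peaks ~106 ms after the cue
#' on successful stops and ~179 ms on failed stops, movement-locked beta
#' desynchronization with a broad gamma increase, a slow (3-5 Hz)
#' cue-evoked wave at Cz, 1/f background activity at 2048 Hz, and blink
#' artifacts leaking from EOG into the scalp channels.
#'
#' @param n_subjects cohort size (default 9).
#' @param n_stop_trials stop trials per subject (default 100).
#' @param metronome_interval ms between metronome sounds (default 900).
#' @param taps_per_trial inclusive integer range of regular taps before
#'   the cue, `c(min, max)` (default 5-9).
#' @param stop_delay stop-cue delay after the last registered tap, ms
#'   (default 707; per-subject values are drawn around this in
#'   [simulate_dataset()]).
#' @param success_prob probability of a successful stop (default 0.55).
#' @param tap_jitter_sd SD of tap timing around the metronome grid, ms.
#' @param tap_mean_offset mean tap-to-sound offset, ms (negative =
#'   anticipatory tapping).
#' @param failed_tap_interval,failed_tap_interval_sd mean/SD (ms) of the
#'   interval between the last regular tap and the unsuccessfully
#'   inhibited tap; 864 +/- 36 ms puts the failed tap ~156 ms after a
#'   707 ms cue, defining the stopping window.
#' @param p_full_given_success probability that a successful stop is a
#'   full stop (< 10% movement extent) rather than an intermediate one.
#' @param gamma_burst list: `center_freq` (Hz), `latency_success`,
#'   `latency_fail`, `latency_sd` (ms), `amp_success`, `amp_fail`
#'   (peak amplitude in units of the broadband background SD), `duration`
#'   (Gaussian-envelope FWHM, ms).
#' @param between_subject list of between-subject SDs: `amp_sd`
#'   (log-normal sigma on burst amplitude), `latency_sd` (ms),
#'   `delay_sd` (ms, stop-cue delay).
#' @param beta_desync_depth fractional movement-locked beta amplitude
#'   reduction (0-1).
#' @param tap_gamma_gain peak fractional broad-gamma increase at taps.
#' @param slow_evoked_amp amplitude of the cue-evoked 3-5 Hz wave at Cz.
#' @param slow_evoked_freq its carrier frequency, Hz.
#' @param blink_rate blinks per minute on the EOG channel.
#' @param eog_leak named per-EEG-channel blink leakage coefficients.
#' @param coupling_amp amplitude of the shared narrow-band gamma
#'   component giving STN-M1 phase coupling; the component is gated off
#'   for 250 ms after each stop cue (connectivity drop).
#' @param noise_exponent 1/f spectral slope of the background.
#' @param sample_rate acquisition rate, Hz (default 2048).
#' @param intertrial_gap s of rest between trials.
#' @param edge_pad s of signal padding before the first and after the
#'   last event (filter-edge region).
#' @param trial_amp_sd log-normal sigma of trial-to-trial burst-amplitude
#'   variability (free parameter of the generator).
#' @param seed integer seed; identical configurations give bit-identical
#'   output.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 9, n_stop_trials = 100,
                       metronome_interval = 900, taps_per_trial = c(5, 9),
                       stop_delay = 707, success_prob = 0.55,
                       tap_jitter_sd = 40, tap_mean_offset = -30,
                       failed_tap_interval = 864,
                       failed_tap_interval_sd = 36,
                       p_full_given_success = 0.45,
                       gamma_burst = list(center_freq = 70,
                                          latency_success = 106,
                                          latency_fail = 179,
                                          latency_sd = 25,
                                          amp_success = 1.2,
                                          amp_fail = 0.45,
                                          duration = 90),
                       between_subject = list(amp_sd = 0.25,
                                              latency_sd = 12,
                                              delay_sd = 49),
                       beta_desync_depth = 0.6, tap_gamma_gain = 1.0,
                       slow_evoked_amp = 1.5, slow_evoked_freq = 4,
                       blink_rate = 8,
                       eog_leak = c(C3 = 0.10, C4 = 0.10, Cz = 0.18,
                                    Fz = 0.35, Pz = 0.08, Oz = 0.05),
                       coupling_amp = 0.25, noise_exponent = 1,
                       sample_rate = 2048, intertrial_gap = 2,
                       edge_pad = 5, trial_amp_sd = 0.2, seed = 1) {
  gamma_default <- eval(formals(sim_config)$gamma_burst)
  gamma_burst <- modifyList(gamma_default, gamma_burst)
  bs_default <- eval(formals(sim_config)$between_subject)
  between_subject <- modifyList(bs_default, between_subject)
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_subjects >= 1, n_stop_trials >= 1,
              metronome_interval > 0, length(taps_per_trial) == 2,
              taps_per_trial[1] >= 1,
              taps_per_trial[2] >= taps_per_trial[1],
              stop_delay > 0, success_prob >= 0, success_prob <= 1,
              p_full_given_success >= 0, p_full_given_success <= 1,
              tap_jitter_sd >= 0, gamma_burst$duration > 0,
              gamma_burst$center_freq > 0, blink_rate >= 0,
              sample_rate > 0, noise_exponent >= 0)
  })
  cfg
}

#' Simulate the behavioral event stream of one subject
#'
#' Each trial holds 5-9 metronome sounds with anticipatory taps
#' (Gaussian jitter around the grid, negative mean offset), a stop cue at
#' `last tap + stop_delay`, a Bernoulli stopping outcome, a latent
#' movement extent per outcome class, and -- for failed stops -- the
#' unsuccessfully inhibited tap. All latent draws (outcome, extent, burst
#' amplitude and latency per trial) are recorded in the returned ground
#' truth.
#'
#' @param cfg a [sim_config()].
#' @return list with `events` ([event_table()]), `trials`
#'   ([trial_table()]) and `truth` (data frame of latent draws; one row
#'   per stop trial).
#' @export
simulate_behavior <- function(cfg = sim_config()) {
  cfg <- validate_sim_config(cfg)
  set.seed(cfg$seed)
  iti <- cfg$metronome_interval / 1000
  delay <- cfg$stop_delay / 1000
  gb <- cfg$gamma_burst

  rows <- list(); truth <- list()
  t0 <- cfg$edge_pad
  for (tr in seq_len(cfg$n_stop_trials) - 1L) {
    n_taps <- sample(seq(cfg$taps_per_trial[1], cfg$taps_per_trial[2]), 1)
    metro <- t0 + (seq_len(n_taps) - 1) * iti
    offsets <- rnorm(n_taps, cfg$tap_mean_offset, cfg$tap_jitter_sd) / 1000
    taps <- metro + offsets
    last_tap <- taps[n_taps]
    stop_time <- last_tap + delay
    success <- runif(1) < cfg$success_prob
    if (success) {
      full <- runif(1) < cfg$p_full_given_success
      extent <- if (full) runif(1, 0, 10) else runif(1, 10, 80)
      outcome <- if (full) "full" else "intermediate"
      fail_tap <- NA_real_
    } else {
      extent <- runif(1, 90, 100)
      outcome <- "failed"
      fail_tap <- last_tap + max(
        rnorm(1, cfg$failed_tap_interval, cfg$failed_tap_interval_sd) / 1000,
        delay + 0.05)
    }
    lat <- (if (success) gb$latency_success else gb$latency_fail) +
      rnorm(1, 0, gb$latency_sd)
    amp_class <- gb$amp_success +
      (gb$amp_fail - gb$amp_success) * min(extent, 100) / 100
    amp <- amp_class * exp(rnorm(1, 0, cfg$trial_amp_sd))
    rows[[length(rows) + 1]] <- data.frame(
      event_type = c(rep("metronome", n_taps), rep("tap_onset", n_taps),
                     "stop_cue",
                     if (!success) "tap_onset"),
      time = c(metro, taps, stop_time, if (!success) fail_tap),
      trial_idx = tr,
      tap_idx = c(seq_len(n_taps), seq_len(n_taps), NA,
                  if (!success) n_taps + 1L))
    truth[[length(truth) + 1]] <- data.frame(
      trial_idx = tr, n_taps = n_taps, last_tap_time = last_tap,
      stop_time = stop_time, success = success, outcome = outcome,
      movement_extent = extent, failed_tap_time = fail_tap,
      burst_latency_ms = lat, burst_amp = amp,
      tap_sound_offset = offsets[n_taps] * 1000)
    t_end <- max(stop_time, fail_tap, na.rm = TRUE)
    t0 <- t_end + cfg$intertrial_gap
  }
  ev <- do.call(rbind, rows)
  events <- event_table(ev$event_type, ev$time, ev$trial_idx, ev$tap_idx)
  truth <- do.call(rbind, truth)
  trials <- trial_table(
    trial_idx = truth$trial_idx, stop_time = truth$stop_time,
    last_tap_time = truth$last_tap_time,
    stop_delay = (truth$stop_time - truth$last_tap_time) * 1000,
    movement_extent = truth$movement_extent, outcome = truth$outcome,
    tap_sound_offset = truth$tap_sound_offset,
    excluded = FALSE)
  list(events = events, trials = trials, truth = truth)
}

# Add amp * gaussian-envelope burst (optionally carried by a sinusoid)
# into sig around `center` (s); modifies only a local window.
add_burst <- function(sig, rate, center, fwhm, amp, freq = NULL,
                      phase = 0) {
  half <- 2.5 * fwhm
  i0 <- max(1L, floor((center - half) * rate) + 1L)
  i1 <- min(length(sig), ceiling((center + half) * rate) + 1L)
  if (i1 < i0) return(sig)
  t <- (seq(i0, i1) - 1) / rate
  env <- amp * gaussian_envelope(t, center, fwhm)
  if (!is.null(freq)) env <- env * sin(2 * pi * freq * (t - center) + phase)
  sig[i0:i1] <- sig[i0:i1] + env
  sig
}

# Piecewise flexion cycle: rest 0, rise to `a`, plateau, descend back.
# Adds segment values into sig over [t_from, t_to).
gon_segment <- function(sig, rate, t_from, t_to, v_from, v_to) {
  i0 <- max(1L, floor(t_from * rate) + 1L)
  i1 <- min(length(sig), floor(t_to * rate))
  if (i1 < i0) return(sig)
  n <- i1 - i0 + 1
  # smooth (half-cosine) interpolation between the two levels
  u <- (1 - cos(pi * seq_len(n) / n)) / 2
  sig[i0:i1] <- v_from + (v_to - v_from) * u
  sig
}

#' Simulate the multichannel signals of one subject
#'
#' Builds a 12-channel recording (C3, C4, Cz, Fz, Pz, Oz EEG; STN_contra,
#' STN_ipsi bipolar LFP; EOG; FDI EMG; pressure; goniometer) at
#' `cfg$sample_rate` whose statistical structure matches what the
#' analysis pipeline assumes: 1/f background on all electrophysiology
#' channels, movement-locked beta decrease and broad gamma increase on
#' the contralateral motor channels, an outcome-coupled post-stop gamma
#' burst on the contralateral STN (earlier and larger on successful
#' stops), a slow cue-evoked wave at Cz regardless of outcome, a shared
#' narrow-band gamma component linking STN and contralateral M1 that is
#' gated off after the cue, blinks on EOG leaking into the EEG, a
#' goniometer trace whose post-cue descent is truncated at the latent
#' movement extent, and pressure pulses for every registered tap
#' (post-cue only in failed trials).
#'
#' @param cfg a [sim_config()].
#' @param events the [event_table()] from [simulate_behavior()].
#' @param truth the ground-truth frame from [simulate_behavior()].
#' @param tapping_hand `"left"` or `"right"`.
#' @param subject_id subject label.
#' @return a [recording()].
#' @export
simulate_signals <- function(cfg, events, truth,
                             tapping_hand = "right", subject_id = "S1") {
  cfg <- validate_sim_config(cfg)
  if (!nrow(events) || !all(events$trial_idx %in% truth$trial_idx))
    stop("events are inconsistent with the supplied ground truth",
         call. = FALSE)
  set.seed(cfg$seed + 1L)
  fs <- cfg$sample_rate
  dur <- max(events$time, truth$failed_tap_time, na.rm = TRUE) +
    cfg$edge_pad
  n <- as.integer(256 * ceiling(dur * fs / 256))
  t <- (seq_len(n) - 1) / fs

  eeg_names <- c("C3", "C4", "Cz", "Fz", "Pz", "Oz")
  ch_names <- c(eeg_names, "STN_contra", "STN_ipsi", "EOG", "FDI",
                "pressure", "goniometer")
  ch_kinds <- c(rep("eeg", 6), "lfp_bipolar", "lfp_bipolar", "eog",
                "emg", "pressure", "goniometer")
  data <- matrix(0, nrow = length(ch_names), ncol = n,
                 dimnames = list(ch_names, NULL))
  ephys <- c(eeg_names, "STN_contra", "STN_ipsi", "FDI")
  for (nm in ephys)
    data[nm, ] <- one_over_f_noise(n, fs, cfg$noise_exponent)

  m1_contra <- if (tapping_hand == "right") "C3" else "C4"
  taps <- events$time[events$event_type == "tap_onset"]
  reg_taps <- events$time[events$event_type == "tap_onset" &
                            !is.na(events$tap_idx)]
  gb <- cfg$gamma_burst

  ## movement-locked beta desynchronization (contralateral M1 + STN)
  beta_env <- rep(1, n)
  for (tp in taps) {
    half <- 0.45
    i0 <- max(1L, floor((tp - half) * fs) + 1L)
    i1 <- min(n, ceiling((tp + half) * fs))
    tt <- (seq(i0, i1) - 1) / fs
    beta_env[i0:i1] <- beta_env[i0:i1] *
      (1 - cfg$beta_desync_depth * gaussian_envelope(tt, tp, 0.3))
  }
  beta_carrier <- sin(2 * pi * 20 * t + runif(1, 0, 2 * pi))
  for (nm in c(m1_contra, "STN_contra"))
    data[nm, ] <- data[nm, ] + 0.4 * beta_env * beta_carrier

  ## movement-locked broad gamma increase (multiplicative on band noise)
  if (cfg$tap_gamma_gain > 0) {
    bp <- signal::butter(3, c(40, 95) / (fs / 2))
    gnoise <- signal::filtfilt(bp, rnorm(n))
    gnoise <- gnoise / sd(gnoise)
    genv <- rep(0, n)
    for (tp in taps) {
      i0 <- max(1L, floor((tp - 0.3) * fs) + 1L)
      i1 <- min(n, ceiling((tp + 0.3) * fs))
      tt <- (seq(i0, i1) - 1) / fs
      genv[i0:i1] <- pmax(genv[i0:i1], gaussian_envelope(tt, tp, 0.2))
    }
    amp_tap_gamma <- 0.15
    for (nm in c(m1_contra, "STN_contra"))
      data[nm, ] <- data[nm, ] +
        amp_tap_gamma * cfg$tap_gamma_gain * genv * gnoise
  }

  ## outcome-coupled post-stop gamma burst on the contralateral STN
  for (i in seq_len(nrow(truth))) {
    center <- truth$stop_time[i] + truth$burst_latency_ms[i] / 1000
    data["STN_contra", ] <- add_burst(
      data["STN_contra", ], fs, center, gb$duration / 1000,
      truth$burst_amp[i], freq = gb$center_freq,
      phase = runif(1, 0, 2 * pi))
  }

  ## shared narrow-band gamma (STN-M1 phase coupling); after each stop
  ## cue the STN side crossfades to an independent same-band component,
  ## destroying the phase relation while preserving band power (the
  ## connectivity drop is a phase phenomenon, not a power artifact)
  if (cfg$coupling_amp > 0) {
    bpc <- signal::butter(3, c(gb$center_freq - 5, gb$center_freq + 5) /
                            (fs / 2))
    shared <- signal::filtfilt(bpc, rnorm(n))
    shared <- shared / sd(shared)
    indep <- signal::filtfilt(bpc, rnorm(n))
    indep <- indep / sd(indep)
    gate <- rep(1, n)
    for (st in truth$stop_time) {
      i0 <- max(1L, floor(st * fs) + 1L)
      i1 <- min(n, ceiling((st + 0.25) * fs))
      gate[i0:i1] <- 0
    }
    gate <- moving_average(gate, max(1, round(0.02 * fs)))
    data[m1_contra, ] <- data[m1_contra, ] + cfg$coupling_amp * shared
    data["STN_contra", ] <- data["STN_contra", ] + cfg$coupling_amp *
      (gate * shared + sqrt(pmax(1 - gate^2, 0)) * indep)
  }

  ## slow cue-evoked wave at Cz (present regardless of outcome)
  for (st in truth$stop_time)
    data["Cz", ] <- add_burst(data["Cz", ], fs, st + 0.15, 0.25,
                              cfg$slow_evoked_amp,
                              freq = cfg$slow_evoked_freq)

  ## blinks: EOG plus per-channel leakage into the EEG
  eog <- 0.5 * one_over_f_noise(n, fs, cfg$noise_exponent)
  blink_src <- rep(0, n)
  n_blinks <- rpois(1, cfg$blink_rate * dur / 60)
  if (n_blinks > 0) {
    btimes <- sort(runif(n_blinks, cfg$edge_pad / 2, dur))
    for (bt in btimes)
      blink_src <- add_burst(blink_src, fs, bt, 0.15, 30)
  }
  data["EOG", ] <- eog + blink_src
  for (nm in eeg_names)
    data[nm, ] <- data[nm, ] + cfg$eog_leak[[nm]] * blink_src

  ## goniometer: flexion cycles, post-cue descent truncated per extent
  gon <- rep(0, n)
  iti <- cfg$metronome_interval / 1000
  for (tr in unique(events$trial_idx)) {
    tr_taps <- sort(events$time[events$event_type == "tap_onset" &
                                  events$trial_idx == tr &
                                  !is.na(events$tap_idx) &
                                  events$tap_idx <=
                                    max(truth$n_taps[truth$trial_idx == tr])])
    a <- 1 * exp(rnorm(1, 0, 0.08))
    if (length(tr_taps) > 1) {
      for (j in seq_len(length(tr_taps) - 1)) {
        t1 <- tr_taps[j]; t2 <- tr_taps[j + 1]
        gon <- gon_segment(gon, fs, t1, t1 + 0.35, 0, a)
        gon <- gon_segment(gon, fs, t1 + 0.35, t2 - 0.25, a, a)
        gon <- gon_segment(gon, fs, t2 - 0.25, t2, a, 0)
      }
    }
    ti <- which(truth$trial_idx == tr)
    last_tap <- truth$last_tap_time[ti]
    extent <- truth$movement_extent[ti] / 100
    down_end <- if (!is.na(truth$failed_tap_time[ti]))
      truth$failed_tap_time[ti] else last_tap + 0.88
    # final cycle: rise, plateau, then a descent truncated at `extent`
    gon <- gon_segment(gon, fs, last_tap, last_tap + 0.35, 0, a)
    gon <- gon_segment(gon, fs, last_tap + 0.35, down_end - 0.25, a, a)
    desc_dur <- 0.25 * min(extent, 1)
    floor_lvl <- a * (1 - min(extent, 1))
    gon <- gon_segment(gon, fs, down_end - 0.25,
                       down_end - 0.25 + desc_dur, a, floor_lvl)
    # hold the truncated posture through the scoring window, then relax
    gon <- gon_segment(gon, fs, down_end - 0.25 + desc_dur,
                       down_end + 1.0, floor_lvl, floor_lvl)
    gon <- gon_segment(gon, fs, down_end + 1.0, down_end + 1.3,
                       floor_lvl, 0)
  }
  gon_noise <- signal::filtfilt(signal::butter(3, 10 / (fs / 2)), rnorm(n))
  data["goniometer", ] <- gon + 0.005 * gon_noise / sd(gon_noise)

  ## pressure pulses for every registered tap
  pres <- rep(0, n)
  for (tp in taps) {
    dur_tap <- max(0.06, rnorm(1, 0.12, 0.015))
    amp <- max(0.5, rnorm(1, 1, 0.1))
    i0 <- floor(tp * fs) + 1L
    i1 <- min(n, i0 + round(dur_tap * fs))
    if (i0 >= 1 && i0 <= n) {
      m <- i1 - i0 + 1
      edge <- max(3L, round(0.01 * fs))
      prof <- rep(amp, m)
      ramp <- seq_len(min(edge, m))
      prof[ramp] <- amp * ramp / length(ramp)
      prof[m + 1 - ramp] <- amp * ramp / length(ramp)
      pres[i0:i1] <- pmax(pres[i0:i1], prof)
    }
  }
  data["pressure", ] <- pres + 0.002 * rnorm(n)

  ## EMG bursts mirror executed downward movements
  for (tp in reg_taps)
    data["FDI", ] <- add_emg_burst(data["FDI", ], fs, tp - 0.05)
  for (i in seq_len(nrow(truth))) {
    if (truth$movement_extent[i] > 10) {
      center <- if (!is.na(truth$failed_tap_time[i]))
        truth$failed_tap_time[i] - 0.05 else truth$last_tap_time[i] + 0.75
      data["FDI", ] <- add_emg_burst(data["FDI", ], fs, center,
                                     amp = truth$movement_extent[i] / 100)
    }
  }

  recording(data, ch_names, ch_kinds, fs, subject_id = subject_id,
            tapping_hand = tapping_hand, reference = "raw")
}

add_emg_burst <- function(sig, rate, center, amp = 1) {
  half <- 0.15
  i0 <- max(1L, floor((center - half) * rate) + 1L)
  i1 <- min(length(sig), ceiling((center + half) * rate))
  if (i1 < i0) return(sig)
  tt <- (seq(i0, i1) - 1) / rate
  env <- gaussian_envelope(tt, center, 0.12)
  sig[i0:i1] <- sig[i0:i1] + 2 * amp * env * rnorm(length(env))
  sig
}

#' Simulate a multi-subject dataset
#'
#' Draws per-subject seeds deterministically from `cfg$seed` and
#' between-subject variation of the stop-cue delay, burst amplitude and
#' burst latency from the configured normal distributions. Three of nine
#' subjects tap with the left hand (the contralateral hemisphere flips
#' accordingly).
#'
#' @param cfg a [sim_config()].
#' @return list of `n_subjects` elements, each with `recording`,
#'   `events`, `trials`, `truth` and `params` (the realized per-subject
#'   parameters).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  cfg <- validate_sim_config(cfg)
  set.seed(cfg$seed)
  ns <- cfg$n_subjects
  seeds <- sample.int(2^31 - 10, ns)
  delays <- pmin(pmax(rnorm(ns, cfg$stop_delay,
                            cfg$between_subject$delay_sd), 550), 900)
  amp_factors <- exp(rnorm(ns, 0, cfg$between_subject$amp_sd))
  lat_offsets <- rnorm(ns, 0, cfg$between_subject$latency_sd)
  hands <- rep("right", ns)
  hands[intersect(c(4, 7, 9), seq_len(ns))] <- "left"  # 3 of 9 left-handed taps

  out <- vector("list", ns)
  for (j in seq_len(ns)) {
    cfg_j <- cfg
    cfg_j$seed <- seeds[j]
    cfg_j$stop_delay <- delays[j]
    cfg_j$gamma_burst$amp_success <- cfg$gamma_burst$amp_success *
      amp_factors[j]
    cfg_j$gamma_burst$amp_fail <- cfg$gamma_burst$amp_fail * amp_factors[j]
    cfg_j$gamma_burst$latency_success <- cfg$gamma_burst$latency_success +
      lat_offsets[j]
    cfg_j$gamma_burst$latency_fail <- cfg$gamma_burst$latency_fail +
      lat_offsets[j]
    beh <- simulate_behavior(cfg_j)
    rec <- simulate_signals(cfg_j, beh$events, beh$truth,
                            tapping_hand = hands[j],
                            subject_id = sprintf("S%d", j))
    out[[j]] <- list(recording = rec, events = beh$events,
                     trials = beh$trials, truth = beh$truth,
                     params = list(seed = seeds[j], stop_delay = delays[j],
                                   amp_factor = amp_factors[j],
                                   latency_offset = lat_offsets[j],
                                   tapping_hand = hands[j]))
  }
  out
}

#' Control-condition configuration
#'
#' Returns a copy of `cfg` with the stop-locked STN gamma burst and the
#' post-cue coupling drop disabled while the slow cue-evoked cortical
#' response is retained -- the signal structure of the condition in which
#' the salient cue is heard but stopping is not attempted.
#'
#' @param cfg a [sim_config()].
#' @return modified `sim_config`.
#' @export
control_config <- function(cfg = sim_config()) {
  cfg$gamma_burst$amp_success <- 0
  cfg$gamma_burst$amp_fail <- 0
  cfg$coupling_amp <- 0
  cfg
}
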