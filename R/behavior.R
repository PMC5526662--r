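#' Behavioral analysis configuration
#'
#' @param arrhythmia_threshold taps deviating more than this many ms from
#'   the nearest metronome sound are flagged arrhythmic (default 300).
#' @param full_stop_threshold movement-extent percentage below which a
#'   stop counts as full (default 10).
#' @param pressure_onset_threshold sensor-unit threshold for tap onset
#'   detection (default 0.5; release hysteresis at half this value).
#' @param goniometer_smoothing optional smoothing window (ms) applied to
#'   the goniometer before velocity estimation (default 20).
#' @return a list of class `behavior_config`.
#' @export
behavior_config <- function(arrhythmia_threshold = 300,
                            full_stop_threshold = 10,
                            pressure_onset_threshold = 0.5,
                            goniometer_smoothing = 20) {
  stopifnot(arrhythmia_threshold > 0, full_stop_threshold > 0,
            pressure_onset_threshold > 0, goniometer_smoothing >= 0)
  structure(list(arrhythmia_threshold = arrhythmia_threshold,
                 full_stop_threshold = full_stop_threshold,
                 pressure_onset_threshold = pressure_onset_threshold,
                 goniometer_smoothing = goniometer_smoothing),
            class = "behavior_config")
}

#' Detect tap onsets and releases from the pressure channel
#'
#' Upward threshold crossings mark onsets; the release (offset) is the
#' subsequent downward crossing of half the threshold (hysteresis guards
#' against chatter at the edge). `down_time` is the finger-contact
#' duration.
#'
#' @param pressure numeric pressure-sensor signal.
#' @param rate sampling rate, Hz.
#' @param cfg a [behavior_config()].
#' @return data frame with `onset`, `offset` (s) and `down_time` (ms);
#'   zero rows when no taps are present.
#' @export
detect_taps <- function(pressure, rate, cfg = behavior_config()) {
  hi <- cfg$pressure_onset_threshold
  lo <- hi / 2
  above <- pressure >= hi
  below <- pressure < lo
  onsets <- integer(0); offsets <- integer(0)
  i <- 1L; n <- length(pressure)
  while (i <= n) {
    nxt <- which(above[i:n])[1]
    if (is.na(nxt)) break
    on <- i + nxt - 1L
    rel <- which(below[on:n])[1]
    off <- if (is.na(rel)) n else on + rel - 1L
    onsets <- c(onsets, on); offsets <- c(offsets, off)
    i <- off + 1L
  }
  data.frame(onset = (onsets - 1) / rate, offset = (offsets - 1) / rate,
             down_time = (offsets - onsets) / rate * 1000)
}

#' Movement extent of a stopping attempt
#'
#' Percentage of the post-cue downward goniometer excursion relative to
#' the amplitude of the preceding upward movement: 0% is a full stop,
#' ~100% a completed (failed-stop) tap; values above 100 are possible.
#' The apex is the flexion-cycle maximum reached just before/at the cue;
#' the post-cue minimum is searched within one metronome interval after
#' the cue.
#'
#' @param gon goniometer signal (full recording or an epoch).
#' @param rate sampling rate, Hz.
#' @param stop_time stop-cue time (s, same time base as `gon`).
#' @param interval tapping interval (s) bounding the search windows.
#' @return list with `extent` (percent, `NA` when the preceding upward
#'   amplitude is degenerate, with `flagged = TRUE`), `upward_amplitude`
#'   and `flagged`.
#' @export
movement_extent <- function(gon, rate, stop_time, interval = 0.9) {
  n <- length(gon)
  idx <- function(t) pmin(pmax(floor(t * rate) + 1L, 1L), n)
  pre <- gon[idx(stop_time - interval):idx(stop_time)]
  # allow the apex to sit marginally after the cue (descent onset)
  apex_win <- gon[idx(stop_time - interval):idx(stop_time + 0.1)]
  post <- gon[idx(stop_time):idx(stop_time + interval)]
  up_amp <- max(pre) - min(pre)
  if (!is.finite(up_amp) || up_amp < 1e-6 * max(abs(gon), 1))
    return(list(extent = NA_real_, upward_amplitude = up_amp,
                flagged = TRUE))
  apex <- max(apex_win)
  excursion <- max(apex - min(post), 0)
  list(extent = 100 * excursion / up_amp, upward_amplitude = up_amp,
       flagged = FALSE)
}

#' Classify a stopping attempt
#'
#' Failed iff the pressure sensor was touched after the cue; otherwise
#' full when the movement extent is below the full-stop threshold, else
#' intermediate. Total on all inputs: the three classes partition the
#' stop trials.
#'
#' @param extent movement extent in percent.
#' @param pressure_touched logical: sensor contact after the cue.
#' @param cfg a [behavior_config()].
#' @return one of `"full"`, `"intermediate"`, `"failed"`.
#' @export
classify_outcome <- function(extent, pressure_touched,
                             cfg = behavior_config()) {
  if (isTRUE(pressure_touched)) return("failed")
  if (!is.na(extent) && extent < cfg$full_stop_threshold) return("full")
  "intermediate"
}

#' Flag arrhythmic taps and exclude affected trials
#'
#' A tap deviating more than the arrhythmia threshold from the nearest
#' metronome sound is flagged; a trial is excluded when a flagged tap
#' precedes its stop cue.
#'
#' @param events an [event_table()].
#' @param cfg a [behavior_config()].
#' @return list with `events` (a `tap_flagged` column added to tap rows)
#'   and `excluded_trials` (integer trial indices).
#' @export
exclude_arrhythmic <- function(events, cfg = behavior_config()) {
  metro <- events$time[events$event_type == "metronome"]
  is_tap <- events$event_type == "tap_onset"
  flag <- rep(NA, nrow(events))
  if (length(metro)) {
    dev <- vapply(events$time[is_tap],
                  function(tt) min(abs(tt - metro)) * 1000, numeric(1))
    flag[is_tap] <- dev > cfg$arrhythmia_threshold
  } else flag[is_tap] <- FALSE
  events$tap_flagged <- flag
  excluded <- integer(0)
  for (tr in unique(events$trial_idx)) {
    sub <- events[events$trial_idx == tr, , drop = FALSE]
    cue <- sub$time[sub$event_type == "stop_cue"]
    if (!length(cue)) next
    if (any(sub$tap_flagged & sub$event_type == "tap_onset" &
              sub$time < min(cue), na.rm = TRUE))
      excluded <- c(excluded, tr)
  }
  list(events = events, excluded_trials = excluded)
}

#' Covariates of the last regular tap before each stop cue
#'
#' Per stop trial: `soundOffset` (tap minus metronome sound, ms; negative
#' = anticipatory), `downTime` (contact duration, ms), `maxPres` (peak
#' pressure during contact), `tapNr` (taps preceding the cue),
#' `peakVelDown`/`peakVelUp` (peak goniometer velocity of the preceding
#' downward/upward movement, units/s) and `upMvmt` (upward amplitude).
#' Velocities use a central-difference derivative after optional
#' smoothing. Metrics whose source channel is absent are `NA`.
#'
#' @param events an [event_table()].
#' @param rec the [recording()] holding pressure and goniometer channels.
#' @param cfg a [behavior_config()].
#' @return data frame, one row per stop trial.
#' @export
tap_metrics <- function(events, rec, cfg = behavior_config()) {
  rate <- rec$sample_rate
  has_pres <- length(channels_of_kind(rec, "pressure")) > 0
  has_gon <- length(channels_of_kind(rec, "goniometer")) > 0
  pres <- if (has_pres)
    channel_data(rec, channels_of_kind(rec, "pressure")[1]) else NULL
  gon <- if (has_gon)
    channel_data(rec, channels_of_kind(rec, "goniometer")[1]) else NULL
  taps_det <- if (has_pres) detect_taps(pres, rate, cfg) else NULL
  if (has_gon && cfg$goniometer_smoothing > 0)
    gon <- moving_average(gon, round(cfg$goniometer_smoothing / 1000 * rate))
  vel <- if (has_gon)
    c(0, (gon[-c(1, 2)] - gon[-c(length(gon) - 1, length(gon))]) /
        (2 / rate), 0) else NULL

  trials <- sort(unique(events$trial_idx[events$event_type == "stop_cue"]))
  out <- lapply(trials, function(tr) {
    sub <- events[events$trial_idx == tr, , drop = FALSE]
    cue <- min(sub$time[sub$event_type == "stop_cue"])
    reg <- sub[sub$event_type == "tap_onset" & sub$time < cue, ,
               drop = FALSE]
    last_tap <- max(reg$time)
    metro <- sub$time[sub$event_type == "metronome"]
    sound_offset <- if (length(metro))
      (last_tap - metro[which.min(abs(metro - last_tap))]) * 1000 else NA
    down_time <- max_pres <- NA_real_
    if (has_pres && nrow(taps_det)) {
      k <- which.min(abs(taps_det$onset - last_tap))
      if (abs(taps_det$onset[k] - last_tap) < 0.15) {
        down_time <- taps_det$down_time[k]
        i0 <- floor(taps_det$onset[k] * rate) + 1
        i1 <- floor(taps_det$offset[k] * rate) + 1
        max_pres <- max(pres[i0:i1])
      }
    }
    peak_vel_down <- peak_vel_up <- up_mvmt <- NA_real_
    if (has_gon) {
      n <- length(gon)
      idx <- function(tt) pmin(pmax(floor(tt * rate) + 1L, 1L), n)
      # preceding cycle: up-movement after the second-to-last tap,
      # descent into the last tap
      win <- idx(last_tap - 0.9):idx(last_tap)
      up_mvmt <- max(gon[win]) - min(gon[win])
      peak_vel_up <- max(vel[win])
      peak_vel_down <- -min(vel[win])
    }
    data.frame(trial_idx = tr, soundOffset = sound_offset,
               downTime = down_time, maxPres = max_pres,
               tapNr = nrow(reg), peakVelDown = peak_vel_down,
               upMvmt = up_mvmt, peakVelUp = peak_vel_up)
  })
  do.call(rbind, out)
}

#' Derive the trial table from signals and events
#'
#' Recomputes per-stop-trial behavioral outcomes from the pressure and
#' goniometer channels: movement extent, outcome class (failed iff the
#' sensor was touched after the cue), tap-to-sound offset of the last
#' regular tap, and the arrhythmia exclusion flag.
#'
#' @param rec a [recording()] with pressure and goniometer channels.
#' @param events an [event_table()].
#' @param cfg a [behavior_config()].
#' @param interval tapping interval in s.
#' @return a [trial_table()].
#' @export
build_trial_table <- function(rec, events, cfg = behavior_config(),
                              interval = 0.9) {
  rate <- rec$sample_rate
  pres <- channel_data(rec, channels_of_kind(rec, "pressure")[1])
  gon <- channel_data(rec, channels_of_kind(rec, "goniometer")[1])
  taps_det <- detect_taps(pres, rate, cfg)
  arr <- exclude_arrhythmic(events, cfg)
  trials <- sort(unique(events$trial_idx[events$event_type == "stop_cue"]))
  rows <- lapply(trials, function(tr) {
    sub <- events[events$trial_idx == tr, , drop = FALSE]
    cue <- min(sub$time[sub$event_type == "stop_cue"])
    reg <- sub$time[sub$event_type == "tap_onset" & sub$time < cue]
    last_tap <- max(reg)
    touched <- any(taps_det$onset > cue &
                     taps_det$onset <= cue + interval)
    me <- movement_extent(gon, rate, cue, interval)
    extent <- if (touched && is.na(me$extent)) 100 else me$extent
    metro <- sub$time[sub$event_type == "metronome"]
    off <- if (length(metro))
      (last_tap - metro[which.min(abs(metro - last_tap))]) * 1000 else NA
    data.frame(trial_idx = tr, stop_time = cue, last_tap_time = last_tap,
               stop_delay = (cue - last_tap) * 1000,
               movement_extent = extent,
               outcome = classify_outcome(me$extent, touched, cfg),
               tap_sound_offset = off,
               excluded = tr %in% arr$excluded_trials || me$flagged)
  })
  df <- do.call(rbind, rows)
  do.call(trial_table, df)
}
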