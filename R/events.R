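#' Typed task event table
#'
#' Time-stamped task events: metronome sounds, tap onsets and stop or
#' continue cues, with trial and within-trial tap indices. Times are
#' seconds from recording start; `tap_idx` counts taps within a trial
#' starting at 1 (it is `NA` for cue rows).
#'
#' @param event_type character vector over
#'   `{"metronome", "tap_onset", "stop_cue", "continue_cue"}`.
#' @param time event times in seconds (>= 0).
#' @param trial_idx integer trial index (>= 0).
#' @param tap_idx integer tap index within trial (>= 1), `NA` for cues.
#' @return a `data.frame` of class `event_table`, sorted by time.
#' @export
event_table <- function(event_type = character(), time = numeric(),
                        trial_idx = integer(), tap_idx = integer()) {
  tbl <- data.frame(event_type = as.character(event_type),
                    time = as.numeric(time),
                    trial_idx = as.integer(trial_idx),
                    tap_idx = as.integer(tap_idx),
                    stringsAsFactors = FALSE)
  tbl <- tbl[order(tbl$time), , drop = FALSE]
  rownames(tbl) <- NULL
  class(tbl) <- c("event_table", "data.frame")
  validate_event_table(tbl)
}

#' Validate event-table invariants
#'
#' Known event types, non-negative times, non-decreasing times within each
#' trial, and every stop cue preceded by at least one tap onset in its
#' trial.
#'
#' @param tbl an [event_table()].
#' @return `tbl`, or an error.
#' @export
validate_event_table <- function(tbl) {
  bad <- setdiff(tbl$event_type, EVENT_TYPES)
  if (length(bad))
    stop("unknown event_type(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  if (any(tbl$time < 0))
    stop("event times must be >= 0 s", call. = FALSE)
  if (any(tbl$trial_idx < 0, na.rm = TRUE))
    stop("trial_idx must be >= 0", call. = FALSE)
  for (tr in unique(tbl$trial_idx)) {
    sub <- tbl[tbl$trial_idx == tr, , drop = FALSE]
    if (is.unsorted(sub$time))
      stop("event times not non-decreasing within trial ", tr, call. = FALSE)
    cue <- sub$time[sub$event_type == "stop_cue"]
    if (length(cue) &&
        !any(sub$event_type == "tap_onset" & sub$time < min(cue)))
      stop("stop_cue in trial ", tr, " has no preceding tap_onset",
           call. = FALSE)
  }
  tbl
}

#' Per-stop-trial behavioral outcome table
#'
#' One row per stop trial: timing of the cue and last regular tap, the
#' stop-signal delay, the post-cue movement extent (percent of the
#' preceding upward movement; 0 = full stop, ~100 = failed stop), the
#' outcome class, the last tap's tap-to-sound offset, and an exclusion
#' flag (arrhythmic tapping before the cue).
#'
#' @param trial_idx integer trial indices.
#' @param stop_time stop-cue times in seconds.
#' @param last_tap_time time of the last regular tap before the cue (s).
#' @param stop_delay stop-signal delay in ms (cue minus last tap).
#' @param movement_extent percent (>= 0; may exceed 100).
#' @param outcome one of `"full"`, `"intermediate"`, `"failed"`.
#' @param tap_sound_offset last tap's offset to its metronome sound in ms
#'   (negative = anticipatory tap before the sound).
#' @param excluded logical exclusion flag.
#' @return a `data.frame` of class `trial_table`.
#' @export
trial_table <- function(trial_idx = integer(), stop_time = numeric(),
                        last_tap_time = numeric(), stop_delay = numeric(),
                        movement_extent = numeric(), outcome = character(),
                        tap_sound_offset = numeric(), excluded = logical()) {
  tbl <- data.frame(trial_idx = as.integer(trial_idx),
                    stop_time = as.numeric(stop_time),
                    last_tap_time = as.numeric(last_tap_time),
                    stop_delay = as.numeric(stop_delay),
                    movement_extent = as.numeric(movement_extent),
                    outcome = as.character(outcome),
                    tap_sound_offset = as.numeric(tap_sound_offset),
                    excluded = as.logical(excluded),
                    stringsAsFactors = FALSE)
  bad <- setdiff(tbl$outcome, OUTCOME_LEVELS)
  if (length(bad))
    stop("unknown outcome(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  if (any(tbl$movement_extent < 0, na.rm = TRUE))
    stop("movement_extent must be >= 0", call. = FALSE)
  class(tbl) <- c("trial_table", "data.frame")
  tbl
}
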