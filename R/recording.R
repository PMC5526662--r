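#' Multichannel recording container
#'
#' A `recording` bundles a channels-by-samples data matrix with per-channel
#' kind labels, the sampling rate and subject/side metadata. All channels
#' share one time base starting at 0 s.
#'
#' @param data numeric matrix, channels x samples.
#' @param names character vector of unique channel names (one per row).
#' @param kinds character vector of channel kinds, each one of
#'   `"eeg"`, `"lfp_bipolar"`, `"lfp_mono"`, `"eog"`, `"emg"`,
#'   `"pressure"`, `"goniometer"`, `"sound"`, `"earlobe"`.
#' @param sample_rate sampling rate in Hz (> 0).
#' @param subject_id subject identifier.
#' @param tapping_hand `"left"` or `"right"`; used downstream to resolve
#'   contra-/ipsilateral channels.
#' @param reference EEG reference scheme: `"raw"`, `"linked_earlobes"` or
#'   `"common_average"`.
#'
#' @return an object of class `recording`.
#' @export
recording <- function(data, names, kinds, sample_rate,
                      subject_id = "S1", tapping_hand = "right",
                      reference = "raw") {
  if (!is.matrix(data)) data <- matrix(data, nrow = length(names))
  storage.mode(data) <- "double"
  rec <- structure(
    list(subject_id = as.character(subject_id),
         channels = data.frame(name = as.character(names),
                               kind = as.character(kinds),
                               stringsAsFactors = FALSE),
         sample_rate = as.numeric(sample_rate),
         data = data,
         tapping_hand = match.arg(tapping_hand, c("left", "right")),
         reference = match.arg(reference,
                               c("raw", "linked_earlobes", "common_average"))),
    class = "recording")
  validate_recording(rec)
}

#' Validate a recording's invariants
#'
#' Checks unique channel names, known kinds, positive sampling rate and a
#' data matrix whose row count matches the channel table (all channels
#' necessarily share one length since they are rows of one matrix).
#'
#' @param rec a [recording()].
#' @return `rec`, invisibly unchanged, or an error.
#' @export
validate_recording <- function(rec) {
  ch <- rec$channels
  if (nrow(ch) == 0L)
    stop("recording has an empty channel list", call. = FALSE)
  if (anyDuplicated(ch$name))
    stop("channel names must be unique", call. = FALSE)
  bad <- setdiff(ch$kind, CHANNEL_KINDS)
  if (length(bad))
    stop("unknown channel kind(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.finite(rec$sample_rate) || rec$sample_rate <= 0)
    stop("sample_rate must be > 0", call. = FALSE)
  if (nrow(rec$data) != nrow(ch))
    stop("data has ", nrow(rec$data), " rows but ", nrow(ch),
         " channels are declared", call. = FALSE)
  rec
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> subject %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$sample_rate,
              ncol(x$data) / x$sample_rate))
  cat(sprintf("  tapping hand: %s, reference: %s\n",
              x$tapping_hand, x$reference))
  k <- split(x$channels$name, x$channels$kind)
  for (kind in names(k))
    cat(sprintf("  %-12s %s\n", kind, paste(k[[kind]], collapse = " ")))
  invisible(x)
}

#' Extract one channel's samples by name
#'
#' @param rec a [recording()].
#' @param name channel name.
#' @return numeric vector of samples.
#' @export
channel_data <- function(rec, name) {
  i <- match(name, rec$channels$name)
  if (is.na(i)) stop("unknown channel: ", name, call. = FALSE)
  rec$data[i, ]
}

#' Names of channels of a given kind
#'
#' @param rec a [recording()].
#' @param kind one of the channel kinds.
#' @return character vector (possibly empty).
#' @export
channels_of_kind <- function(rec, kind) {
  rec$channels$name[rec$channels$kind == kind]
}

#' Time vector of a recording
#'
#' @param rec a [recording()].
#' @return numeric vector of sample times in seconds (recording start = 0).
#' @export
recording_times <- function(rec) {
  (seq_len(ncol(rec$data)) - 1) / rec$sample_rate
}

#' Contralateral and ipsilateral channel resolution
#'
#' Maps `C3`/`C4` and `STN_left`/`STN_right` style names onto contra- and
#' ipsilateral roles given the tapping hand (the hemisphere contralateral
#' to the moving hand drives it).
#'
#' @param rec a [recording()].
#' @return named list with elements `m1_contra`, `m1_ipsi` (may be `NA`
#'   when EEG is absent) and, when present, `stn_contra`, `stn_ipsi`.
#' @export
lateralize_channels <- function(rec) {
  nm <- rec$channels$name
  left_hand <- rec$tapping_hand == "left"
  pick <- function(a, b) {  # a = left-hemisphere name, b = right-hemisphere
    contra <- if (left_hand) b else a
    ipsi <- if (left_hand) a else b
    c(contra = if (contra %in% nm) contra else NA_character_,
      ipsi = if (ipsi %in% nm) ipsi else NA_character_)
  }
  m1 <- pick("C3", "C4")
  out <- list(m1_contra = unname(m1["contra"]), m1_ipsi = unname(m1["ipsi"]))
  if (any(grepl("^STN", nm))) {
    # synthetic recordings label the STN bipolars by role directly
    if ("STN_contra" %in% nm) {
      out$stn_contra <- "STN_contra"
      out$stn_ipsi <- if ("STN_ipsi" %in% nm) "STN_ipsi" else NA_character_
    } else {
      stn <- pick("STN_left", "STN_right")
      out$stn_contra <- unname(stn["contra"])
      out$stn_ipsi <- unname(stn["ipsi"])
    }
  }
  out
}
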