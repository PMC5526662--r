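#' Preprocessing configuration
#'
#' @param dc_time_constant RC time constant (s) of the first-order
#'   high-pass used for DC removal; default 2 s.
#' @param eog_lowpass_hz EOG low-pass cutoff before amplitude matching
#'   (Hz); default 40.
#' @param filter_order Butterworth order of the EOG low-pass; default 6.
#' @param target_rate_stage1 rate (Hz) the conditioned signals are
#'   down-sampled to before spectral analysis; default 1000.
#' @param reference EEG re-referencing scheme: `"linked_earlobes"` when
#'   earlobe channels were recorded, otherwise `"common_average"` over the
#'   scalp channels.
#' @return a list of class `preproc_config`.
#' @export
preproc_config <- function(dc_time_constant = 2, eog_lowpass_hz = 40,
                           filter_order = 6, target_rate_stage1 = 1000,
                           reference = c("common_average",
                                         "linked_earlobes")) {
  stopifnot(dc_time_constant > 0, eog_lowpass_hz > 0,
            filter_order >= 1, target_rate_stage1 > 0)
  structure(list(dc_time_constant = dc_time_constant,
                 eog_lowpass_hz = eog_lowpass_hz,
                 filter_order = as.integer(filter_order),
                 target_rate_stage1 = target_rate_stage1,
                 reference = match.arg(reference)),
            class = "preproc_config")
}

#' Remove the DC component with a first-order high-pass
#'
#' First-order IIR high-pass with RC = `time_constant`, applied forward
#' only (acquisition-style AC coupling). A constant input decays as
#' `exp(-t / time_constant)`; a 10 Hz oscillation passes essentially
#' unattenuated (cutoff 1/(2*pi*RC) ~ 0.08 Hz for the default 2 s).
#'
#' @param x numeric signal.
#' @param rate sampling rate in Hz.
#' @param time_constant RC constant in seconds (> 0).
#' @return high-passed signal, same length.
#' @export
remove_dc <- function(x, rate, time_constant = 2) {
  stopifnot(time_constant > 0)
  a <- time_constant / (time_constant + 1 / rate)
  as.numeric(signal::filter(c(a, -a), c(1, -a), x))
}

#' Re-reference the EEG channels of a recording
#'
#' `"common_average"` subtracts the per-sample mean of the scalp EEG
#' channels from each EEG channel (EOG/EMG/LFP and sensor channels are
#' untouched). `"linked_earlobes"` subtracts the mean of the earlobe
#' channels and requires channels of kind `"earlobe"`.
#'
#' @param rec a [recording()].
#' @param scheme `"common_average"` or `"linked_earlobes"`.
#' @return the re-referenced recording with its `reference` field updated.
#'   A recording without EEG channels is returned unchanged.
#' @export
rereference <- function(rec, scheme = c("common_average",
                                        "linked_earlobes")) {
  scheme <- match.arg(scheme)
  eeg <- which(rec$channels$kind == "eeg")
  if (!length(eeg)) return(rec)
  if (scheme == "linked_earlobes") {
    ears <- which(rec$channels$kind == "earlobe")
    if (!length(ears))
      stop("linked_earlobes reference requires earlobe channels",
           call. = FALSE)
    ref <- colMeans(rec$data[ears, , drop = FALSE])
  } else {
    ref <- colMeans(rec$data[eeg, , drop = FALSE])
  }
  rec$data[eeg, ] <- sweep(rec$data[eeg, , drop = FALSE], 2, ref)
  rec$reference <- scheme
  rec
}

#' Append bipolar derivations of monopolar channels
#'
#' For each `(A, B)` pair a channel `A-B` of kind `"lfp_bipolar"` is
#' appended (common-mode signal shared by both contacts cancels). The
#' monopolar channels are retained.
#'
#' @param rec a [recording()].
#' @param pairs list of length-2 character vectors `c(A, B)`.
#' @return recording with the bipolar channels appended.
#' @export
derive_bipolars <- function(rec, pairs) {
  for (p in pairs) {
    ia <- match(p[1], rec$channels$name)
    ib <- match(p[2], rec$channels$name)
    if (is.na(ia) || is.na(ib))
      stop("unknown channel in bipolar pair: ",
           paste(p, collapse = "-"), call. = FALSE)
    rec$data <- rbind(rec$data, rec$data[ia, ] - rec$data[ib, ])
    rec$channels <- rbind(rec$channels,
                          data.frame(name = paste0(p[1], "-", p[2]),
                                     kind = "lfp_bipolar"))
  }
  validate_recording(rec)
}

#' Regress blink artifacts out of an EEG channel
#'
#' The EOG is low-pass filtered (Butterworth, zero-phase) and subtracted
#' from the EEG after amplitude matching. The scale is the least-squares
#' projection coefficient `<eeg, e> / <e, e>` (`e` = filtered EOG) --
#' the closed-form optimum of the squared-residual objective, so the
#' corrected channel never has more residual variance than the input.
#'
#' @param eeg_signal,eog_signal equal-length numeric vectors.
#' @param rate sampling rate in Hz.
#' @param cfg a [preproc_config()].
#' @return list with `cleaned` (corrected EEG) and `scale`.
#' @export
remove_eog <- function(eeg_signal, eog_signal, rate,
                       cfg = preproc_config()) {
  stopifnot(length(eeg_signal) == length(eog_signal))
  bf <- signal::butter(cfg$filter_order,
                       cfg$eog_lowpass_hz / (rate / 2), type = "low")
  e <- signal::filtfilt(bf, eog_signal)
  ss <- sum(e * e)
  if (ss <= .Machine$double.eps * length(e)) {
    warning("EOG channel has (near) zero variance; scale set to 0")
    return(list(cleaned = eeg_signal, scale = 0))
  }
  scale <- sum(eeg_signal * e) / ss
  list(cleaned = eeg_signal - scale * e, scale = scale)
}

#' Condition a recording for spectral analysis
#'
#' Runs the standard chain: DC removal (electrophysiology channels only;
#' sensor channels keep their baselines), EEG re-referencing, resampling
#' to `cfg$target_rate_stage1`, and per-channel EOG regression. A
#' recording without EEG channels skips the EEG-specific stages rather
#' than failing. The first and last `2 * dc_time_constant` seconds are
#' flagged as filter-edge regions; epochs must not touch them.
#'
#' @param rec a [recording()].
#' @param cfg a [preproc_config()].
#' @param bipolar_pairs optional list of monopolar pairs passed to
#'   [derive_bipolars()] before resampling.
#' @return list with `rec` (conditioned recording), `eog_scales` (named
#'   per-EEG-channel scales, or `NULL`) and `flagged_edge_s` (seconds at
#'   each end to exclude from epoching).
#' @export
preprocess_recording <- function(rec, cfg = preproc_config(),
                                 bipolar_pairs = NULL) {
  ephys <- rec$channels$kind %in% c("eeg", "eog", "emg",
                                    "lfp_mono", "lfp_bipolar", "earlobe")
  for (i in which(ephys))
    rec$data[i, ] <- remove_dc(rec$data[i, ], rec$sample_rate,
                               cfg$dc_time_constant)
  has_eeg <- any(rec$channels$kind == "eeg")
  if (has_eeg) rec <- rereference(rec, cfg$reference)
  if (!is.null(bipolar_pairs)) rec <- derive_bipolars(rec, bipolar_pairs)
  if (rec$sample_rate != cfg$target_rate_stage1) {
    new_data <- apply(rec$data, 1, resample_signal,
                      rate_in = rec$sample_rate,
                      rate_out = cfg$target_rate_stage1)
    rec$data <- t(new_data)
    rec$sample_rate <- cfg$target_rate_stage1
  }
  eog_scales <- NULL
  eog_ch <- channels_of_kind(rec, "eog")
  if (has_eeg && length(eog_ch)) {
    eog <- channel_data(rec, eog_ch[1])
    eeg_names <- channels_of_kind(rec, "eeg")
    eog_scales <- numeric(0)
    for (nm in eeg_names) {
      fit <- remove_eog(channel_data(rec, nm), eog, rec$sample_rate, cfg)
      rec$data[match(nm, rec$channels$name), ] <- fit$cleaned
      eog_scales[nm] <- fit$scale
    }
  }
  list(rec = validate_recording(rec), eog_scales = eog_scales,
       flagged_edge_s = 2 * cfg$dc_time_constant)
}
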