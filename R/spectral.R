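#' Hilbert filterbank specification
#'
#' Low-frequency power (3-40 Hz) comes from 3 Hz-wide bands stepped by
#' 1 Hz; high-frequency power (50-120 Hz) from 10 Hz-wide bands stepped
#' by 2 Hz. Each band is an order-6 Butterworth band-pass applied
#' forward-backward (zero phase).
#'
#' @param low_range,low_width,low_step low-band layout in Hz.
#' @param high_range,high_width,high_step high-band layout in Hz.
#' @param order total Butterworth order (default 6).
#' @return list of class `filterbank_spec` with a `bands` data frame
#'   (`lo`, `hi`, `center`, `set`).
#' @export
filterbank_spec <- function(low_range = c(3, 40), low_width = 3,
                            low_step = 1, high_range = c(50, 120),
                            high_width = 10, high_step = 2, order = 6) {
  lo_l <- seq(low_range[1], low_range[2] - low_width, by = low_step)
  lo_h <- seq(high_range[1], high_range[2] - high_width, by = high_step)
  bands <- rbind(
    data.frame(lo = lo_l, hi = lo_l + low_width, set = "low"),
    data.frame(lo = lo_h, hi = lo_h + high_width, set = "high"))
  bands$center <- (bands$lo + bands$hi) / 2
  stopifnot(all(bands$lo > 0))
  structure(list(bands = bands, order = as.integer(order)),
            class = "filterbank_spec")
}

#' Band-limited Hilbert power of a signal
#'
#' Band-pass filters (order-6 Butterworth, forward-backward, unit gain at
#' band center) and returns the squared magnitude of the analytic signal
#' -- the instantaneous power envelope. `envelope_power = 1` gives the
#' plain envelope for sensitivity checks.
#'
#' @param x numeric signal.
#' @param rate sampling rate, Hz.
#' @param band `c(lo, hi)` in Hz, inside `(0, rate/2)`.
#' @param order total filter order (even; default 6).
#' @param envelope_power exponent applied to the envelope (default 2).
#' @return numeric power time series, same length as `x`.
#' @export
band_power <- function(x, rate, band, order = 6, envelope_power = 2) {
  if (band[1] <= 0 || band[2] >= rate / 2 || band[2] <= band[1])
    stop(sprintf("band [%g, %g] Hz is invalid for rate %g Hz",
                 band[1], band[2], rate), call. = FALSE)
  bf <- signal::butter(max(1L, order %/% 2), band / (rate / 2))
  filtered <- signal::filtfilt(bf, x)
  Mod(analytic_signal(filtered))^envelope_power
}

#' Smooth a power time series and down-sample it
#'
#' Centered 100 ms moving average followed by decimation to
#' `target_rate` (the moving average provides the anti-alias smoothing).
#' With `target_rate = rate` only the smoothing is applied.
#'
#' @param power numeric power series.
#' @param rate sampling rate of `power`, Hz.
#' @param window_ms smoothing window width, ms (default 100).
#' @param target_rate output rate, Hz (default 200; must divide `rate`).
#' @return numeric series at `target_rate`.
#' @export
smooth_power <- function(power, rate, window_ms = 100, target_rate = 200) {
  stopifnot(window_ms > 0)
  sm <- moving_average(power, round(window_ms / 1000 * rate))
  if (target_rate == rate) return(sm)
  dec <- rate / target_rate
  if (abs(dec - round(dec)) > 1e-9)
    stop("target_rate must divide rate", call. = FALSE)
  sm[seq(1, length(sm), by = round(dec))]
}

#' Time-frequency map container
#'
#' @param values frequency x time numeric matrix.
#' @param freqs band center frequencies, Hz (rows).
#' @param times sample times in s, strictly increasing (columns); for
#'   epoched maps these are relative to the alignment event.
#' @param alignment one of `"none"`, `"stop_cue"`, `"tap_onset"`,
#'   `"virtual_stop"`.
#' @param units `"raw_power"`, `"percent_change"`, `"ispc"` or
#'   `"ispc_change"`.
#' @param subject_id subject label.
#' @return object of class `tf_map`.
#' @export
tf_map <- function(values, freqs, times, alignment = "none",
                   units = "raw_power", subject_id = "") {
  values <- as.matrix(values)
  if (nrow(values) != length(freqs) || ncol(values) != length(times))
    stop("tf_map axes do not match the value matrix", call. = FALSE)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("tf_map times must be strictly increasing", call. = FALSE)
  structure(list(values = values, freqs = as.numeric(freqs),
                 times = as.numeric(times), alignment = alignment,
                 units = units, subject_id = subject_id),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf(
    "<tf_map> %d freqs (%g-%g Hz) x %d times (%.3f..%.3f s), %s, align=%s\n",
    length(x$freqs), min(x$freqs), max(x$freqs), length(x$times),
    min(x$times), max(x$times), x$units, x$alignment))
  invisible(x)
}

#' Filterbank power of one channel as a tf_map
#'
#' Runs [band_power()] for every filterbank band and [smooth_power()] on
#' each row, yielding a frequency x time map at `target_rate`.
#'
#' @param x numeric signal.
#' @param rate sampling rate of `x`, Hz.
#' @param fb a [filterbank_spec()] (or its `bands` subset).
#' @param window_ms smoothing window, ms.
#' @param target_rate output rate, Hz.
#' @param subject_id subject label carried in the map.
#' @return a [tf_map()] with units `"raw_power"`.
#' @export
tf_power <- function(x, rate, fb = filterbank_spec(), window_ms = 100,
                     target_rate = 200, subject_id = "") {
  bands <- if (inherits(fb, "filterbank_spec")) fb$bands else fb
  order <- if (inherits(fb, "filterbank_spec")) fb$order else 6L
  rows <- lapply(seq_len(nrow(bands)), function(i) {
    p <- band_power(x, rate, c(bands$lo[i], bands$hi[i]), order = order)
    smooth_power(p, rate, window_ms, target_rate)
  })
  vals <- do.call(rbind, rows)
  tf_map(vals, bands$center, (seq_len(ncol(vals)) - 1) / target_rate,
         units = "raw_power", subject_id = subject_id)
}

#' Epoch a tf_map around alignment events
#'
#' Cuts `[window[1], window[2])` (half-open, seconds relative to each
#' alignment time) out of a continuous map. Epochs exceeding the map (or
#' entering `edge_s` of either end) are dropped with a message. The
#' `virtual_stop` alignment used for the last regular tap is
#' `previous tap + stop_delay` -- where the cue would have occurred one
#' tap earlier.
#'
#' @param tf a continuous [tf_map()].
#' @param align_times numeric alignment times (s).
#' @param window `c(start, end)` in s relative to alignment.
#' @param edge_s flagged edge region to avoid, s.
#' @return 3-D array `trial x freq x time` with attributes `times`
#'   (relative), `freqs` and `kept` (indices of retained alignments).
#' @export
epoch_tf <- function(tf, align_times, window, edge_s = 0) {
  fs <- 1 / diff(tf$times[1:2])
  rel <- seq(round(window[1] * fs), round(window[2] * fs) - 1)
  keep <- logical(length(align_times))
  mats <- vector("list", length(align_times))
  lo_t <- min(tf$times) + edge_s
  hi_t <- max(tf$times) - edge_s
  for (k in seq_along(align_times)) {
    i0 <- round((align_times[k] - tf$times[1]) * fs) + 1
    cols <- i0 + rel
    if (cols[1] < 1 || cols[length(cols)] > ncol(tf$values) ||
        align_times[k] + window[1] < lo_t ||
        align_times[k] + window[2] > hi_t) {
      message(sprintf("epoch at %.2f s outside usable range; dropped",
                      align_times[k]))
      next
    }
    keep[k] <- TRUE
    mats[[k]] <- tf$values[, cols, drop = FALSE]
  }
  mats <- mats[keep]
  if (!length(mats)) stop("no epochs inside the recording", call. = FALSE)
  arr <- array(NA_real_, c(length(mats), length(tf$freqs), length(rel)))
  for (k in seq_along(mats)) arr[k, , ] <- mats[[k]]
  structure(arr, times = rel / fs, freqs = tf$freqs, kept = which(keep))
}

#' Normalize epochs to the regular-tap baseline
#'
#' Converts power to percent change relative to the per-frequency mean
#' across all regular-tap epochs and times (the paper-style baseline
#' excludes tap one and the last tap before each cue -- the caller
#' selects which taps enter `baseline_epochs`).
#'
#' @param epochs 3-D `trial x freq x time` array from [epoch_tf()].
#' @param baseline_epochs 3-D array of regular-tap epochs.
#' @return array like `epochs` with values `100 * (P / baseline_f - 1)`.
#' @export
normalize_to_regular_taps <- function(epochs, baseline_epochs) {
  baseline <- apply(baseline_epochs, 2, mean)
  if (any(!is.finite(baseline)) || any(baseline <= 0))
    stop("regular-tap baseline is zero or undefined", call. = FALSE)
  out <- epochs
  for (f in seq_along(baseline))
    out[, f, ] <- 100 * (epochs[, f, ] / baseline[f] - 1)
  attributes(out) <- attributes(epochs)
  out
}

#' Select the bipolar LFP montage with the strongest gamma reactivity
#'
#' For each candidate bipolar signal, the 60-90 Hz power time course is
#' epoched around every tap (window spanning twice the tapping interval),
#' the median across taps is taken, and the modulation index is
#' `(max - min) / mean` of that median time course. The candidate with
#' the largest index is selected.
#'
#' @param candidates named list of numeric signals (bipolar derivations).
#' @param rate sampling rate, Hz.
#' @param tap_times regular tap times, s (>= 2 required).
#' @param tapping_interval tapping interval, s (default 0.9).
#' @param band gamma band used for selection (default `c(60, 90)`).
#' @return list with `selected` (name), `index` (named vector of
#'   modulation indices) and `timecourses`.
#' @export
select_bipolar <- function(candidates, rate, tap_times,
                           tapping_interval = 0.9, band = c(60, 90)) {
  if (!length(candidates)) stop("no candidate bipolars", call. = FALSE)
  if (length(tap_times) < 2)
    stop("bipolar selection needs at least two taps", call. = FALSE)
  idx <- numeric(length(candidates))
  names(idx) <- names(candidates)
  tcs <- list()
  for (nm in names(candidates)) {
    p <- band_power(candidates[[nm]], rate, band)
    p <- smooth_power(p, rate, 100, target_rate = rate)
    fs <- rate
    rel <- seq(round(-tapping_interval * fs),
               round(tapping_interval * fs) - 1)
    ep <- sapply(tap_times, function(tp) {
      i0 <- round(tp * fs) + 1
      cols <- i0 + rel
      if (cols[1] < 1 || cols[length(cols)] > length(p))
        return(rep(NA_real_, length(rel)))
      p[cols]
    })
    med <- apply(ep, 1, median, na.rm = TRUE)
    idx[nm] <- (max(med) - min(med)) / mean(med)
    tcs[[nm]] <- med
  }
  list(selected = names(which.max(idx)), index = idx, timecourses = tcs)
}

#' Average a tf_map (or epoch array) over a frequency band
#'
#' Mean over the frequency bins whose centers lie in `[lo, hi]`.
#'
#' @param tf a [tf_map()] or a 3-D `trial x freq x time` array with a
#'   `freqs` attribute.
#' @param band `c(lo, hi)` in Hz.
#' @return numeric time series (for `tf_map`) or `trial x time` matrix.
#' @export
band_timecourse <- function(tf, band) {
  freqs <- if (inherits(tf, "tf_map")) tf$freqs else attr(tf, "freqs")
  sel <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(sel))
    stop("band does not overlap any frequency bin", call. = FALSE)
  if (inherits(tf, "tf_map")) {
    colMeans(tf$values[sel, , drop = FALSE])
  } else {
    apply(tf[, sel, , drop = FALSE], c(1, 3), mean)
  }
}

#' Peak latency of a band time course
#'
#' Argmax latency within a half-open search window; ties resolve to the
#' earliest sample. An all-NaN window yields `NA`.
#'
#' @param tc numeric time course.
#' @param times sample times (s) of `tc`.
#' @param window `c(start, end)` in s.
#' @return latency in ms, or `NA`.
#' @export
peak_latency <- function(tc, times, window = c(0, 0.156)) {
  sel <- which(times >= window[1] & times < window[2])
  if (!length(sel)) stop("window outside the time axis", call. = FALSE)
  vals <- tc[sel]
  if (all(is.na(vals))) return(NA_real_)
  times[sel[which.max(vals)]] * 1000
}

#' Stop-window end from behavioral data
#'
#' The analysis window after the cue ends at the dataset's mean
#' failed-tap latency (time from cue to the unsuccessfully inhibited
#' tap). Falls back to `default` when no failed trials exist.
#'
#' @param trials a [trial_table()] (or truth frame) with `stop_time`;
#'   failed-tap times are taken from `events`.
#' @param events an [event_table()].
#' @param default fallback in s (0.156).
#' @return window end in s.
#' @export
stop_window_end <- function(trials, events, default = 0.156) {
  lat <- c()
  for (i in seq_len(nrow(trials))) {
    if (trials$outcome[i] != "failed") next
    tr <- trials$trial_idx[i]
    cue <- trials$stop_time[i]
    post <- events$time[events$event_type == "tap_onset" &
                          events$trial_idx == tr & events$time > cue]
    if (length(post)) lat <- c(lat, min(post) - cue)
  }
  if (!length(lat)) return(default)
  mean(lat)
}
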