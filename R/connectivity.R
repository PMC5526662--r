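#' ISPC analysis specification
#'
#' Window widths follow the cycle-count rationale: 200 ms for 50-120 Hz
#' and 250 ms for 6-40 Hz (bands below 6 Hz are excluded -- 250 ms would
#' contain barely one cycle). Windows slide in 10 ms steps and are
#' timestamped at their centers; maps are normalized to the -350..0 ms
#' pre-cue baseline.
#'
#' @param window_high_ms window width for >= 50 Hz bands, ms.
#' @param window_low_ms window width for < 50 Hz bands, ms.
#' @param step_ms window step, ms.
#' @param low_freq_cutoff lowest admissible band center, Hz.
#' @param baseline `c(start, end)` of the pre-cue baseline, s.
#' @param time_range `c(start, end)` of window centers relative to the
#'   cue, s.
#' @return list of class `ispc_spec`.
#' @export
ispc_spec <- function(window_high_ms = 200, window_low_ms = 250,
                      step_ms = 10, low_freq_cutoff = 6,
                      baseline = c(-0.35, 0), time_range = c(-0.35, 0.16)) {
  stopifnot(window_high_ms > 0, window_low_ms > 0, step_ms > 0,
            step_ms <= window_high_ms, step_ms <= window_low_ms)
  structure(list(window_high_ms = window_high_ms,
                 window_low_ms = window_low_ms, step_ms = step_ms,
                 low_freq_cutoff = low_freq_cutoff, baseline = baseline,
                 time_range = time_range),
            class = "ispc_spec")
}

#' Instantaneous phase of a band-limited signal
#'
#' Angle of the analytic signal of the band-passed series (same
#' Butterworth filterbank design as the power analysis). Values are
#' wrapped to `(-pi, pi]`.
#'
#' @inheritParams band_power
#' @return numeric phase series in radians.
#' @export
instantaneous_phase <- function(x, rate, band, order = 6) {
  if (band[1] <= 0 || band[2] >= rate / 2 || band[2] <= band[1])
    stop(sprintf("band [%g, %g] Hz is invalid for rate %g Hz",
                 band[1], band[2], rate), call. = FALSE)
  bf <- signal::butter(max(1L, order %/% 2), band / (rate / 2))
  Arg(analytic_signal(signal::filtfilt(bf, x)))
}

#' Intersite phase clustering of two phase series
#'
#' Modulus of the mean unit phasor of the phase differences,
#' `|sum_t exp(i (phi_a_t - phi_b_t)) / n|`: 0 for uniformly scattered
#' differences, 1 for a fixed phase relation. Amplitude-independent and
#' invariant under adding a common phase to both series.
#'
#' @param phase_a,phase_b equal-length phase series (radians), n >= 2.
#' @return ISPC value in `[0, 1]`.
#' @export
ispc <- function(phase_a, phase_b) {
  if (length(phase_a) != length(phase_b) || length(phase_a) < 2)
    stop("ISPC needs two equal-length series with n >= 2", call. = FALSE)
  Mod(mean(exp(1i * (phase_a - phase_b))))
}

#' Windowed ISPC maps between a seed and target channels
#'
#' For every filterbank band (centers above the low-frequency cutoff)
#' and every trial, ISPC is computed over fixed-width windows slid in
#' `step_ms` steps across the peri-cue epoch, then averaged over trials.
#' Window width is 200 ms for bands at or above 50 Hz and 250 ms below.
#'
#' @param seed numeric seed-channel signal (e.g. contralateral STN).
#' @param targets named list of target signals (e.g. EEG channels).
#' @param rate sampling rate, Hz.
#' @param align_times stop-cue times, s.
#' @param spec an [ispc_spec()].
#' @param fb a [filterbank_spec()].
#' @param subject_id label carried into the maps.
#' @return named list of [tf_map()]s (units `"ispc"`, times = window
#'   centers relative to the cue).
#' @export
ispc_map <- function(seed, targets, rate, align_times,
                     spec = ispc_spec(), fb = filterbank_spec(),
                     subject_id = "") {
  bands <- fb$bands[fb$bands$center >= spec$low_freq_cutoff, ]
  centers <- seq(spec$time_range[1], spec$time_range[2],
                 by = spec$step_ms / 1000)
  need_pre <- abs(spec$time_range[1]) + spec$window_low_ms / 2000
  need_post <- spec$time_range[2] + spec$window_low_ms / 2000
  n <- length(seed)
  ok <- align_times - need_pre > 0 &
    align_times + need_post < (n - 1) / rate
  if (!all(ok)) {
    if (!any(ok)) stop("all epochs are too short for the ISPC windows",
                       call. = FALSE)
    align_times <- align_times[ok]
  }
  out <- lapply(targets, function(x)
    matrix(0, nrow(bands), length(centers)))
  for (b in seq_len(nrow(bands))) {
    w_s <- (if (bands$set[b] == "high" || bands$center[b] >= 50)
      spec$window_high_ms else spec$window_low_ms) / 1000
    half <- round(w_s * rate / 2)
    ph_seed <- instantaneous_phase(seed, rate,
                                   c(bands$lo[b], bands$hi[b]), fb$order)
    for (nm in names(targets)) {
      ph_t <- instantaneous_phase(targets[[nm]], rate,
                                  c(bands$lo[b], bands$hi[b]), fb$order)
      u <- exp(1i * (ph_seed - ph_t))
      cs <- cumsum(u)
      acc <- numeric(length(centers))
      for (tr in align_times) {
        ci <- round((tr + centers) * rate) + 1
        a <- pmax(ci - half, 1)
        bnd <- pmin(ci + half - 1, length(u))
        s <- cs[bnd] - c(0, cs)[a]
        acc <- acc + Mod(s) / (bnd - a + 1)
      }
      out[[nm]][b, ] <- acc / length(align_times)
    }
  }
  lapply(out, function(v)
    tf_map(v, bands$center, centers, alignment = "stop_cue",
           units = "ispc", subject_id = subject_id))
}

#' Baseline-normalize an ISPC map
#'
#' Subtracts the per-frequency mean ISPC over the pre-cue baseline
#' window, putting the no-change null at 0 for the downstream
#' against-zero cluster test. `mode = "ratio"` divides instead.
#'
#' @param map a [tf_map()] with units `"ispc"`.
#' @param baseline `c(start, end)` in s (default -0.35..0).
#' @param mode `"difference"` (default) or `"ratio"`.
#' @return a [tf_map()] with units `"ispc_change"`.
#' @export
normalize_ispc <- function(map, baseline = c(-0.35, 0),
                           mode = c("difference", "ratio")) {
  mode <- match.arg(mode)
  sel <- which(map$times >= baseline[1] & map$times <= baseline[2])
  if (!length(sel)) stop("no baseline windows in map", call. = FALSE)
  base <- rowMeans(map$values[, sel, drop = FALSE])
  vals <- if (mode == "difference") map$values - base
  else map$values / base
  tf_map(vals, map$freqs, map$times, alignment = map$alignment,
         units = "ispc_change", subject_id = map$subject_id)
}
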