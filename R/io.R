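#' Write a recording to disk
#'
#' The native container is a JSON sidecar header (`<base>.json`: channel
#' names, kinds, sampling rate, subject metadata, payload layout) plus a
#' channel-major little-endian float64 payload (`<base>.dat`). Output is
#' byte-deterministic for identical input; NaN samples survive the round
#' trip bit-exactly.
#'
#' @param rec a [recording()].
#' @param path base path; a trailing `.json` or `.dat` extension is
#'   stripped, then `<base>.json` and `<base>.dat` are written.
#' @return `path` base, invisibly.
#' @seealso [read_signals()]
#' @export
write_signals <- function(rec, path) {
  rec <- validate_recording(rec)
  base <- sub("\\.(json|dat)$", "", path)
  header <- list(
    format = "stopgamma-signals",
    version = 1L,
    subject_id = rec$subject_id,
    sample_rate = rec$sample_rate,
    n_samples = ncol(rec$data),
    tapping_hand = rec$tapping_hand,
    reference = rec$reference,
    channel_names = rec$channels$name,
    channel_kinds = rec$channels$kind,
    payload = list(file = paste0(basename(base), ".dat"),
                   dtype = "float64", byte_order = "little",
                   order = "channel_major"))
  json <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  con <- file(paste0(base, ".json"), open = "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(paste0(as.character(json), "\n")), con)
  dat <- file(paste0(base, ".dat"), open = "wb")
  on.exit(close(dat), add = TRUE)
  # channel-major: channel 1's samples first. The matrix is channels x
  # samples, so write the transpose column-wise.
  writeBin(as.vector(t(rec$data)), dat, size = 8, endian = "little")
  invisible(base)
}

#' Read a recording from disk
#'
#' Counterpart of [write_signals()]; `read_signals(write_signals(rec, p))`
#' returns a bit-identical recording. A missing header field raises a
#' format error; a payload whose length disagrees with the declared
#' channel/sample counts raises an integrity error.
#'
#' @param path base path or the `.json` header path.
#' @return a [recording()].
#' @export
read_signals <- function(path) {
  base <- sub("\\.(json|dat)$", "", path)
  hpath <- paste0(base, ".json")
  if (!file.exists(hpath)) stop("header not found: ", hpath, call. = FALSE)
  header <- jsonlite::fromJSON(hpath, simplifyVector = TRUE)
  required <- c("channel_names", "channel_kinds", "sample_rate", "n_samples",
                "payload")
  missing <- setdiff(required, names(header))
  if (length(missing))
    stop("signal header is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (length(header$channel_names) == 0L)
    stop("signal header declares an empty channel list", call. = FALSE)
  dpath <- file.path(dirname(hpath), header$payload$file)
  n_chan <- length(header$channel_names)
  n_samp <- as.integer(header$n_samples)
  n_expect <- n_chan * n_samp
  n_avail <- file.info(dpath)$size / 8
  if (!isTRUE(n_avail == n_expect))
    stop(sprintf(
      "payload integrity error: %d channels x %d samples declared but %s values stored",
      n_chan, n_samp, format(n_avail)), call. = FALSE)
  con <- file(dpath, open = "rb")
  on.exit(close(con), add = TRUE)
  raw <- readBin(con, "double", n = n_expect, size = 8, endian = "little")
  data <- t(matrix(raw, nrow = n_samp, ncol = n_chan))
  recording(data, header$channel_names, header$channel_kinds,
            header$sample_rate,
            subject_id = header$subject_id %||% "S1",
            tapping_hand = header$tapping_hand %||% "right",
            reference = header$reference %||% "raw")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read/write event tables as TSV
#'
#' Events are stored as tab-separated text with a header row
#' (`event_type`, `time`, `trial_idx`, `tap_idx`). Rows are sorted
#' ascending by time on read regardless of on-disk order; unknown event
#' types or negative times are rejected.
#'
#' @param tbl an [event_table()].
#' @param path TSV file path.
#' @return `read_events` returns an [event_table()]; `write_events`
#'   returns `path` invisibly.
#' @export
write_events <- function(tbl, path) {
  stopifnot(inherits(tbl, "event_table"))
  write.table(as.data.frame(tbl), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("event_type", "time", "trial_idx", "tap_idx")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("event file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  event_table(raw$event_type, raw$time, raw$trial_idx, raw$tap_idx)
}

#' Read/write trial tables as TSV
#'
#' @param tbl a [trial_table()].
#' @param path TSV file path.
#' @return `read_trials` returns a [trial_table()]; `write_trials`
#'   returns `path` invisibly.
#' @export
write_trials <- function(tbl, path) {
  stopifnot(inherits(tbl, "trial_table"))
  write.table(as.data.frame(tbl), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  do.call(trial_table, raw[c("trial_idx", "stop_time", "last_tap_time",
                             "stop_delay", "movement_extent", "outcome",
                             "tap_sound_offset", "excluded")])
}
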