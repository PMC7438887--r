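#' @useDynLib spikefuse, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median quantile rbinom rnorm rpois runif sd setNames
#' @importFrom utils head tail
NULL

#' The five gesture classes
#'
#' Class labels for the sign-language hand gestures the toolkit classifies,
#' in canonical order (class index 1..5).
#' @export
GESTURES <- c("pinky", "elle", "yo", "index", "thumb")

#' Construct a DVS event stream
#'
#' An event stream is the address-event representation (AER) of a dynamic
#' vision sensor: a time-ordered sequence of (t, x, y, p) records where `t`
#' is a timestamp in microseconds, `(x, y)` the pixel address (0-based,
#' x = column, y = row, origin top-left) and `p` the polarity (1 = ON,
#' brightness increase; 0 = OFF, decrease).
#'
#' @param t numeric vector of timestamps in microseconds, non-decreasing.
#' @param x,y integer pixel coordinates, `0 <= x < width`, `0 <= y < height`.
#' @param p polarity, 0 or 1.
#' @param width,height sensor dimensions in pixels.
#' @return An object of class `event_stream`.
#' @export
event_stream <- function(t = numeric(), x = integer(), y = integer(),
                         p = integer(), width = 128L, height = 128L) {
  n <- length(t)
  if (length(x) != n || length(y) != n || length(p) != n)
    stop("t, x, y, p must have equal length")
  ev <- structure(
    list(t = as.numeric(t), x = as.integer(x), y = as.integer(y),
         p = as.integer(p), width = as.integer(width),
         height = as.integer(height)),
    class = "event_stream")
  validate_event_stream(ev)
}

validate_event_stream <- function(ev) {
  if (ev$width <= 0L || ev$height <= 0L) stop("sensor dimensions must be positive")
  if (length(ev$t) > 0L) {
    if (is.unsorted(ev$t)) stop("validation error: timestamps must be non-decreasing")
    if (any(ev$x < 0L | ev$x >= ev$width))
      stop("validation error: x coordinate out of [0, width)")
    if (any(ev$y < 0L | ev$y >= ev$height))
      stop("validation error: y coordinate out of [0, height)")
    if (any(!(ev$p %in% c(0L, 1L)))) stop("validation error: polarity must be 0 or 1")
  }
  ev
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("<event_stream> %d events, %dx%d px, span %.1f ms\n",
              length(x$t), x$width, x$height,
              if (length(x$t)) diff(range(x$t)) / 1000 else 0))
  invisible(x)
}

#' Number of events in a stream
#' @param ev an `event_stream`.
#' @export
n_events <- function(ev) length(ev$t)

#' Construct an EMG recording
#'
#' Multi-channel surface-EMG sampled by a Myo-class armband: unitless
#' unsigned 8-bit "activation" values, 8 channels at 200 Hz by default.
#'
#' @param samples channels x time numeric matrix, values in `[0, 255]`.
#' @param rate sampling rate in Hz.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(samples, rate = 200) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1L)
  if (rate <= 0) stop("rate must be > 0")
  if (length(samples) && (min(samples) < 0 || max(samples) > 255))
    stop("EMG values must lie in the unsigned 8-bit range [0, 255]")
  structure(list(samples = samples, rate = rate,
                 channels = nrow(samples)),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channels x %d samples @ %g Hz (%.0f ms)\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              1000 * ncol(x$samples) / x$rate))
  invisible(x)
}

#' Construct a labelled two-modality gesture sample
#'
#' One 200 ms (by default) chunk of synchronized EMG and DVS data with its
#' gesture label and provenance identifiers. Both modalities cover the same
#' duration window, re-based to start at t = 0.
#'
#' @param emg an `emg_recording` chunk.
#' @param dvs an `event_stream` chunk.
#' @param label one of [GESTURES].
#' @param duration_ms chunk duration in milliseconds.
#' @param subject,session,repetition,chunk_index integer identifiers
#'   (`chunk_index` is 0-based: chunk k spans `[k*d, (k+1)*d)` ms of the
#'   parent recording).
#' @export
gesture_sample <- function(emg, dvs, label, duration_ms = 200,
                           subject = 1L, session = 1L, repetition = 1L,
                           chunk_index = 0L) {
  if (!label %in% GESTURES)
    stop("label must be one of: ", paste(GESTURES, collapse = ", "))
  structure(list(emg = emg, dvs = dvs, label = label,
                 duration_ms = duration_ms, subject = as.integer(subject),
                 session = as.integer(session),
                 repetition = as.integer(repetition),
                 chunk_index = as.integer(chunk_index)),
            class = "gesture_sample")
}

#' Dataset manifest
#'
#' Describes the layout of a gesture dataset: counts per factor and the
#' chunking geometry. Total sample count is the product of the five counts.
#'
#' @param n_subjects,n_sessions,n_repetitions,n_gestures,n_chunks_per_recording
#'   layout counts; defaults are the deposited dataset's
#'   21 x 3 x 5 x 5 x 10 layout.
#' @param recording_duration_s duration of each gesture recording in seconds.
#' @param chunk_duration_ms duration of each chunk in milliseconds.
#' @export
dataset_manifest <- function(n_subjects = 21L, n_sessions = 3L,
                             n_repetitions = 5L, n_gestures = 5L,
                             n_chunks_per_recording = 10L,
                             recording_duration_s = 2,
                             chunk_duration_ms = 200) {
  m <- structure(list(n_subjects = as.integer(n_subjects),
                      n_sessions = as.integer(n_sessions),
                      n_repetitions = as.integer(n_repetitions),
                      n_gestures = as.integer(n_gestures),
                      n_chunks_per_recording = as.integer(n_chunks_per_recording),
                      recording_duration_s = recording_duration_s,
                      chunk_duration_ms = chunk_duration_ms),
                 class = "dataset_manifest")
  if (m$chunk_duration_ms * m$n_chunks_per_recording >
      m$recording_duration_s * 1000)
    stop("chunks do not fit in the recording duration")
  m
}

#' Total number of samples described by a manifest
#' @param manifest a `dataset_manifest`.
#' @export
n_samples <- function(manifest) {
  with(manifest, n_subjects * n_sessions * n_repetitions * n_gestures *
         n_chunks_per_recording)
}

## ---------------------------------------------------------------------------
## CSV interchange formats.
## Event CSV: first line "<width>,<height>", then one "t_us,x,y,p" row per
## event. EMG CSV: first line "<rate_hz>", then one row of 8 (or C)
## comma-separated integers per time sample.
## ---------------------------------------------------------------------------

#' Read an event stream from CSV
#'
#' Format: a header line `width,height` (two integers) followed by one
#' `t_us,x,y,p` row per event. Malformed rows are reported with their line
#' number; coordinates and timestamp order are validated.
#'
#' @param path file path.
#' @return an `event_stream`.
#' @export
load_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("parse error at line 1: missing header")
  hdr <- suppressWarnings(as.numeric(strsplit(lines[[1]], ",")[[1]]))
  if (length(hdr) != 2L || anyNA(hdr))
    stop("parse error at line 1: expected 'width,height'")
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L)
    return(event_stream(width = hdr[1], height = hdr[2]))
  fields <- strsplit(body, ",")
  bad <- which(lengths(fields) != 4L)
  if (length(bad))
    stop("parse error at line ", bad[1] + 1L, ": expected 4 fields 't_us,x,y,p'")
  m <- suppressWarnings(matrix(as.numeric(unlist(fields)), ncol = 4L,
                               byrow = TRUE))
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1L, any))
    stop("parse error at line ", bad[1] + 1L, ": non-numeric field")
  }
  event_stream(t = m[, 1], x = m[, 2], y = m[, 3], p = m[, 4],
               width = hdr[1], height = hdr[2])
}

#' Write an event stream to CSV
#' @param ev an `event_stream`.
#' @param path file path.
#' @export
write_events <- function(ev, path) {
  lines <- c(paste0(ev$width, ",", ev$height),
             if (length(ev$t))
               paste(format(ev$t, scientific = FALSE, trim = TRUE),
                     ev$x, ev$y, ev$p, sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read an EMG recording from CSV
#'
#' Format: a header line with the sampling rate in Hz, then one row per time
#' sample with comma-separated integer channel values.
#' @param path file path.
#' @return an `emg_recording`.
#' @export
load_emg <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("parse error at line 1: missing rate header")
  rate <- suppressWarnings(as.numeric(lines[[1]]))
  if (is.na(rate)) stop("parse error at line 1: expected sampling rate in Hz")
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L)
    return(emg_recording(matrix(numeric(), nrow = 0L, ncol = 0L), rate = rate))
  fields <- strsplit(body, ",")
  nc <- lengths(fields)
  if (any(nc != nc[1]))
    stop("parse error at line ", which(nc != nc[1])[1] + 1L,
         ": inconsistent channel count")
  m <- suppressWarnings(matrix(as.numeric(unlist(fields)), nrow = nc[1]))
  if (anyNA(m)) stop("parse error: non-numeric EMG value")
  emg_recording(m, rate = rate)  # channels x time
}

#' Write an EMG recording to CSV
#' @param rec an `emg_recording`.
#' @param path file path.
#' @export
write_emg <- function(rec, path) {
  lines <- c(format(rec$rate, scientific = FALSE, trim = TRUE),
             if (ncol(rec$samples))
               apply(rec$samples, 2L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Chunking
## ---------------------------------------------------------------------------

#' Cut full recordings into fixed-duration two-modality samples
#'
#' Each recording is cut into `n_chunks_per_recording` contiguous,
#' non-overlapping chunks of `chunk_duration_ms`, aligned across modalities.
#' Chunk k covers the half-open window `[k*d, (k+1)*d)` — milliseconds for
#' event timestamps, the corresponding half-open sample-index range for EMG —
#' so no sample or event is counted twice. Events beyond the chunked span
#' (if any) are dropped; the 1 s relax period between gestures is assumed
#' already stripped from stored recordings.
#'
#' @param recordings list of records, each a list with fields `emg`
#'   (`emg_recording`), `dvs` (`event_stream`), `label`, `subject`,
#'   `session`, `repetition`.
#' @param manifest a `dataset_manifest`; the recording count must equal
#'   `n_subjects * n_sessions * n_repetitions * n_gestures`.
#' @return list of [gesture_sample()] objects of length [n_samples()].
#' @export
chunk_dataset <- function(recordings, manifest) {
  n_rec_expected <- with(manifest, n_subjects * n_sessions * n_repetitions *
                           n_gestures)
  if (length(recordings) != n_rec_expected)
    stop("expected ", n_rec_expected, " recordings, got ", length(recordings))
  d_ms <- manifest$chunk_duration_ms
  k_max <- manifest$n_chunks_per_recording
  out <- vector("list", n_rec_expected * k_max)
  pos <- 0L
  for (ri in seq_along(recordings)) {
    rec <- recordings[[ri]]
    spc <- d_ms * rec$emg$rate / 1000          # EMG samples per chunk
    if (spc != round(spc))
      stop("chunk duration is not a whole number of EMG samples")
    need <- spc * k_max
    if (ncol(rec$emg$samples) < need)
      stop("recording ", ri, " too short: ", ncol(rec$emg$samples),
           " EMG samples, need ", need)
    ev <- rec$dvs
    for (k in seq_len(k_max) - 1L) {
      i0 <- k * spc + 1L
      emg_chunk <- emg_recording(
        rec$emg$samples[, i0:(i0 + spc - 1L), drop = FALSE],
        rate = rec$emg$rate)
      t0 <- k * d_ms * 1000
      t1 <- (k + 1) * d_ms * 1000
      sel <- ev$t >= t0 & ev$t < t1
      dvs_chunk <- event_stream(ev$t[sel] - t0, ev$x[sel], ev$y[sel],
                                ev$p[sel], ev$width, ev$height)
      pos <- pos + 1L
      out[[pos]] <- gesture_sample(emg_chunk, dvs_chunk, rec$label,
                                   duration_ms = d_ms,
                                   subject = rec$subject,
                                   session = rec$session,
                                   repetition = rec$repetition,
                                   chunk_index = k)
    }
  }
  out
}
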