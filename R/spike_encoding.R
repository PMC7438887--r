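#' Delta-modulator configuration
#'
#' Parameters of the delta-modulator ADC used to convert sampled EMG into
#' UP/DOWN spike trains. The raw unsigned 8-bit signal is first normalized
#' to `[-1, 1)` via `(v - 128)/128` (the sensor is unitless, and the
#' threshold is only meaningful on a normalized scale), then linearly
#' interpolated by `interpolation_factor` to increase temporal resolution
#' before thresholding.
#'
#' @param threshold positive spike threshold delta on the normalized signal.
#' @param interpolation_factor integer oversampling factor (>= 1).
#' @export
delta_mod_config <- function(threshold = 0.05, interpolation_factor = 3500L) {
  if (threshold <= 0) stop("threshold must be > 0")
  interpolation_factor <- as.integer(interpolation_factor)
  if (is.na(interpolation_factor) || interpolation_factor < 1L)
    stop("interpolation_factor must be an integer >= 1")
  structure(list(threshold = threshold,
                 interpolation_factor = interpolation_factor),
            class = "delta_mod_config")
}

#' Normalize raw 8-bit EMG values
#'
#' Fixed map from the unsigned 8-bit range to `[-1, 1)`: `(v - 128)/128`.
#' @param v raw values in `[0, 255]`.
#' @export
normalize_emg <- function(v) (v - 128) / 128

#' Encode an EMG recording into UP/DOWN spike trains
#'
#' Per channel, independently: the signal is normalized, linearly
#' interpolated by the configured factor, and tracked by a reference `r`
#' initialized to the first sample. Whenever the interpolated signal exceeds
#' `r` by more than the threshold delta an UP spike is emitted and
#' `r <- r + delta`; symmetrically a DOWN spike with `r <- r - delta`. At
#' most one spike is emitted per interpolated point; spike times are the
#' interpolated-point times in microseconds. A single-sample recording has
#' no derivative and yields empty trains.
#'
#' @param rec an [emg_recording()].
#' @param cfg a [delta_mod_config()].
#' @return An object of class `spike_train_pair`: per-channel lists
#'   `up` and `down` of strictly increasing spike times (microseconds),
#'   plus the normalized initial value `x0` per channel and the duration.
#' @export
delta_modulate <- function(rec, cfg = delta_mod_config()) {
  if (!inherits(rec, "emg_recording")) stop("rec must be an emg_recording")
  if (ncol(rec$samples) == 0L) stop("rec is empty")
  C <- nrow(rec$samples)
  up <- down <- vector("list", C)
  x0 <- numeric(C)
  for (c in seq_len(C)) {
    s <- normalize_emg(rec$samples[c, ])
    x0[c] <- s[1]
    enc <- delta_mod_encode_cpp(s, rec$rate, cfg$interpolation_factor,
                                cfg$threshold)
    up[[c]] <- enc$up
    down[[c]] <- enc$down
  }
  structure(list(up = up, down = down, x0 = x0,
                 duration_us = 1e6 * ncol(rec$samples) / rec$rate,
                 channels = C, cfg = cfg),
            class = "spike_train_pair")
}

#' Delta-modulate an already-normalized signal
#'
#' Lower-level single-channel entry point of [delta_modulate()]: `x` is
#' taken as-is (no 8-bit normalization). The trigger condition is
#' `|s - r| >= delta` on the interpolated signal, so a ramp covering
#' `range` emits exactly `floor(range/delta)` UP spikes.
#'
#' @param x numeric signal (one channel).
#' @param rate_hz sampling rate of `x`.
#' @param cfg a [delta_mod_config()].
#' @return list `(up, down)` of spike times in microseconds.
#' @export
delta_encode <- function(x, rate_hz, cfg = delta_mod_config()) {
  delta_mod_encode_cpp(as.numeric(x), rate_hz, cfg$interpolation_factor,
                       cfg$threshold)
}

#' Reconstruct the encoded signal from UP/DOWN spike trains
#'
#' Piecewise-constant reconstruction
#' `r(t) = x(0) + delta * (N_up(t) - N_down(t))`, where `N_up(t)` counts UP
#' spikes with time `<= t`. Evaluated at the requested times.
#'
#' @param trains a `spike_train_pair` from [delta_modulate()].
#' @param cfg the [delta_mod_config()] used for encoding (defaults to the
#'   one stored in `trains`).
#' @param at numeric vector of evaluation times in microseconds.
#' @return channels x length(at) matrix of reconstructed values.
#' @export
reconstruct <- function(trains, cfg = trains$cfg, at) {
  delta <- cfg$threshold
  C <- trains$channels
  out <- matrix(0, nrow = C, ncol = length(at))
  for (c in seq_len(C)) {
    n_up <- findInterval(at, trains$up[[c]])
    n_dn <- findInterval(at, trains$down[[c]])
    out[c, ] <- trains$x0[c] + delta * (n_up - n_dn)
  }
  out
}

#' Crop an event stream to a window centered on the activity
#'
#' The window center is the per-coordinate median of the event addresses
#' (robust to background noise events), clamped so the `size x size` window
#' lies fully in-sensor. Retained events are re-based to `[0, size)^2`; all
#' others are dropped. An empty stream yields an empty stream with the
#' window at the sensor center.
#'
#' @param ev an [event_stream()].
#' @param size window side length in pixels (default 40).
#' @return a cropped `event_stream` of dimensions `size x size`.
#' @export
crop_events <- function(ev, size = 40L) {
  size <- as.integer(size)
  if (size > ev$width || size > ev$height)
    stop("crop size exceeds sensor dimensions")
  if (length(ev$t) == 0L) {
    return(event_stream(width = size, height = size))
  }
  cx <- median(ev$x)
  cy <- median(ev$y)
  x0 <- max(0L, min(ev$width - size, as.integer(round(cx - size / 2))))
  y0 <- max(0L, min(ev$height - size, as.integer(round(cy - size / 2))))
  sel <- ev$x >= x0 & ev$x < x0 + size & ev$y >= y0 & ev$y < y0 + size
  event_stream(ev$t[sel], ev$x[sel] - x0, ev$y[sel] - y0, ev$p[sel],
               width = size, height = size)
}

#' Subsample an event stream into four half-resolution streams
#'
#' Stream k (k = 0..3) receives the events whose coordinates have parity
#' `(x mod 2, y mod 2) = (k mod 2, floor(k/2))`, mapped to
#' `(floor(x/2), floor(y/2))`. The four streams partition the input; each
#' has half the spatial resolution (e.g. 40x40 -> four 20x20 streams, one
#' per crossbar core).
#'
#' @param ev an [event_stream()] with even dimensions.
#' @return list of four `event_stream`s (k = 0..3 in list positions 1..4).
#' @export
subsample_quad <- function(ev) {
  if (ev$width %% 2L || ev$height %% 2L)
    stop("subsample_quad requires even sensor dimensions")
  lapply(0:3, function(k) {
    px <- k %% 2L
    py <- k %/% 2L
    sel <- (ev$x %% 2L == px) & (ev$y %% 2L == py)
    event_stream(ev$t[sel], ev$x[sel] %/% 2L, ev$y[sel] %/% 2L, ev$p[sel],
                 width = ev$width %/% 2L, height = ev$height %/% 2L)
  })
}

#' Spike raster constructor
#'
#' A channels x ticks matrix of non-negative spike counts on a regular tick
#' grid (1 ms by default) — the common input format of the SNN simulator.
#'
#' @param counts channels x ticks matrix of non-negative integer counts.
#' @param tick tick duration in milliseconds.
#' @param layout free-text description of the channel layout.
#' @param dims optional spatial dims `c(planes, height, width)` for image
#'   rasters.
#' @export
spike_raster <- function(counts, tick = 1, layout = "", dims = NULL) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  structure(list(counts = counts, tick = tick, layout = layout, dims = dims),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d channels x %d ticks (%g ms tick), %s spikes [%s]\n",
              nrow(x$counts), ncol(x$counts), x$tick,
              format(sum(x$counts)), x$layout))
  invisible(x)
}

#' Bin spike trains or events onto the tick grid
#'
#' Each spike at time t (ms) lands in tick `floor(t / tick)`. Spikes at or
#' beyond `duration_ms` are dropped (their count is reported via a message).
#'
#' For a `spike_train_pair` the layout is 2C channels interleaved per EMG
#' channel: row 2c-1 = channel c UP, row 2c = channel c DOWN. For an
#' `event_stream` the layout is two polarity planes (ON plane first) in
#' row-major pixel order: channel index `plane*H*W + y*W + x + 1` with
#' plane 0 = ON, 1 = OFF; with `merge_polarity = TRUE` a single plane of
#' `H*W` channels is produced (ON/OFF treated equally, as on crossbar
#' MLP cores).
#'
#' @param x a `spike_train_pair` or `event_stream`.
#' @param tick tick duration in milliseconds (default 1).
#' @param duration_ms total raster duration in milliseconds.
#' @param merge_polarity for event streams: merge ON/OFF into one plane.
#' @return a [spike_raster()] with `ceiling(duration_ms / tick)` ticks.
#' @export
rasterize <- function(x, tick = 1, duration_ms, merge_polarity = FALSE) {
  UseMethod("rasterize")
}

.bin_spikes <- function(ch, t_ms, n_ch, n_ticks, tick) {
  dropped <- sum(t_ms >= n_ticks * tick | t_ms < 0)
  if (dropped > 0) {
    keep <- t_ms < n_ticks * tick & t_ms >= 0
    ch <- ch[keep]
    t_ms <- t_ms[keep]
    message(dropped, " spike(s) outside [0, duration) dropped")
  }
  counts <- matrix(0L, nrow = n_ch, ncol = n_ticks)
  if (length(ch)) {
    idx <- ch + n_ch * floor(t_ms / tick)   # 1-based channel, 0-based tick
    tab <- tabulate(idx, nbins = n_ch * n_ticks)
    counts[] <- tab
  }
  counts
}

#' @rdname rasterize
#' @export
rasterize.spike_train_pair <- function(x, tick = 1, duration_ms,
                                       merge_polarity = FALSE) {
  C <- x$channels
  n_ticks <- as.integer(ceiling(duration_ms / tick))
  ch <- integer(0)
  t_ms <- numeric(0)
  for (c in seq_len(C)) {
    ch <- c(ch, rep.int(2L * c - 1L, length(x$up[[c]])),
            rep.int(2L * c, length(x$down[[c]])))
    t_ms <- c(t_ms, x$up[[c]] / 1000, x$down[[c]] / 1000)
  }
  counts <- .bin_spikes(ch, t_ms, 2L * C, n_ticks, tick)
  spike_raster(counts, tick = tick,
               layout = sprintf("%d EMG channels x {UP, DOWN}", C))
}

#' @rdname rasterize
#' @export
rasterize.event_stream <- function(x, tick = 1, duration_ms,
                                   merge_polarity = FALSE) {
  n_ticks <- as.integer(ceiling(duration_ms / tick))
  hw <- x$height * x$width
  if (merge_polarity) {
    ch <- x$y * x$width + x$x + 1L
    n_ch <- hw
    layout <- sprintf("%dx%d merged-polarity pixel map", x$height, x$width)
    dims <- c(1L, x$height, x$width)
  } else {
    plane <- 1L - x$p                        # ON plane first
    ch <- plane * hw + x$y * x$width + x$x + 1L
    n_ch <- 2L * hw
    layout <- sprintf("2 polarity planes x %dx%d (ON first)",
                      x$height, x$width)
    dims <- c(2L, x$height, x$width)
  }
  counts <- .bin_spikes(ch, x$t / 1000, n_ch, n_ticks, tick)
  spike_raster(counts, tick = tick, layout = layout, dims = dims)
}

#' Total spike count per channel of a raster
#' @param raster a [spike_raster()].
#' @export
spike_counts <- function(raster) rowSums(raster$counts)
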