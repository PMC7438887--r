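## Seeded synthetic data with the structure of the benchmark recordings:
## 2 s two-modality gesture recordings organised as subjects x sessions x
## repetitions x gestures, cut downstream into 200 ms chunks. The EMG model
## is amplitude-modulated Gaussian noise with gesture-dependent per-channel
## activation envelopes, 8-bit quantized; the DVS model emits events from a
## per-gesture hand-edge template under rigid jitter motion, with ON/OFF
## polarity following the motion sign plus uniform background noise. The
## defaults make the visual modality more informative than EMG (as in the
## measured benchmark) — a qualitative, not quantitative, emulation.

#' Synthetic dataset configuration
#'
#' @param manifest a [dataset_manifest()] (defaults to a reduced
#'   2-subject layout; pass the full 21-subject manifest for the complete
#'   structure).
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @param difficulty in `[0, 1)`: 0 = maximally distinct classes; higher
#'   values mix per-gesture EMG profiles and DVS templates toward a common
#'   average, lowering attainable accuracy.
#' @param emg_amplitude peak per-channel modulation amplitude (8-bit units).
#' @param emg_noise_sd baseline (rest) EMG noise, 8-bit units.
#' @param emg_rotation per-session armband rotation amplitude, in channels
#'   (the armband is re-donned every session; this drives the cross-session
#'   EMG generalization gap).
#' @param dvs_rate_hz template event rate (events/s over the whole hand).
#' @param dvs_noise_rate_hz uniform background noise event rate.
#' @param jitter_px amplitude of the rigid camera jitter, pixels.
#' @export
synth_config <- function(manifest = dataset_manifest(n_subjects = 2L),
                         seed = 1L, difficulty = 0.3,
                         emg_amplitude = 40, emg_noise_sd = 2,
                         emg_rotation = 1.5,
                         dvs_rate_hz = 4000, dvs_noise_rate_hz = 300,
                         jitter_px = 5L) {
  structure(list(manifest = manifest, seed = as.integer(seed),
                 difficulty = difficulty, emg_amplitude = emg_amplitude,
                 emg_noise_sd = emg_noise_sd, emg_rotation = emg_rotation, dvs_rate_hz = dvs_rate_hz,
                 dvs_noise_rate_hz = dvs_noise_rate_hz,
                 jitter_px = as.integer(jitter_px)),
            class = "synth_config")
}

# thick line stroke between two points, as (x, y) pixel pairs
stroke <- function(x0, y0, x1, y1, width = 2L) {
  n <- max(abs(x1 - x0), abs(y1 - y0)) + 1L
  xs <- round(seq(x0, x1, length.out = n))
  ys <- round(seq(y0, y1, length.out = n))
  px <- do.call(rbind, lapply(seq_len(width) - 1L, function(o)
    cbind(xs + o, ys)))
  unique(px)
}

#' Per-gesture hand-edge template on the 128x128 sensor
#'
#' Edge-pixel sets (what an event camera sees of a static shape under
#' motion): a palm outline common to all classes plus the extended fingers
#' that distinguish them — pinky only, elle (thumb + index), yo (thumb +
#' pinky), index only, thumb only.
#'
#' @param gesture one of [GESTURES].
#' @return integer matrix with columns x, y.
#' @export
gesture_template <- function(gesture) {
  palm <- rbind(stroke(54, 60, 76, 60), stroke(54, 90, 76, 90),
                stroke(54, 60, 54, 90), stroke(76, 60, 76, 90))
  index_f <- stroke(57, 32, 57, 59)
  middle_f <- stroke(63, 28, 63, 59)
  ring_f <- stroke(69, 30, 69, 59)
  pinky_f <- stroke(75, 36, 75, 59)
  thumb_f <- stroke(53, 59, 38, 44)
  fingers <- switch(gesture,
                    pinky = pinky_f,
                    elle = rbind(thumb_f, index_f),
                    yo = rbind(thumb_f, pinky_f),
                    index = index_f,
                    thumb = thumb_f,
                    stop("unknown gesture: ", gesture))
  unique(rbind(palm, fingers))
}

# all-fingers template used as the "confusable" mixture target
template_common <- function() {
  unique(do.call(rbind, lapply(GESTURES, gesture_template)))
}

# gesture-dependent 8-channel amplitude profile (Gaussian bump over the
# electrode ring), mixed toward the across-gesture mean by `difficulty`.
# `rotation` shifts the bump around the ring (in channels): the armband is
# re-donned every session, so electrode positions differ between sessions
# — the main reason cross-session EMG generalizes worse than vision.
emg_profile <- function(gesture, amplitude, difficulty, rotation = 0) {
  centers <- setNames(c(1.2, 2.8, 4.4, 6.0, 7.6), GESTURES)
  # broad bumps: neighbouring gestures share most of their active channels,
  # making EMG the weaker modality (as in the measured benchmark)
  prof <- function(ctr) amplitude * exp(-((1:8 - ctr - rotation)^2) / (2 * 2.5^2))
  own <- prof(centers[[gesture]])
  avg <- rowMeans(vapply(centers, prof, numeric(8)))
  (1 - difficulty) * own + difficulty * avg
}

gen_emg_recording <- function(gesture, cfg, gain, rotation = 0) {
  n <- cfg$manifest$recording_duration_s * 200
  amp <- emg_profile(gesture, cfg$emg_amplitude, cfg$difficulty,
                     rotation) * gain
  env <- pmin(seq_len(n) / (0.15 * 200), 1)       # 150 ms activation ramp
  z <- matrix(rnorm(8 * n), 8, n)
  v <- 128 + amp * rep(env, each = 8) * z +
    matrix(rnorm(8 * n, sd = cfg$emg_noise_sd), 8, n)
  emg_recording(pmin(pmax(round(v), 0), 255), rate = 200)
}

gen_dvs_recording <- function(gesture, cfg) {
  dur_s <- cfg$manifest$recording_duration_s
  tmpl <- gesture_template(gesture)
  if (cfg$difficulty > 0) {
    comm <- template_common()
    n_mix <- round(cfg$difficulty * nrow(tmpl))
    if (n_mix > 0) {
      drop <- sample.int(nrow(tmpl), n_mix)
      add <- comm[sample.int(nrow(comm), n_mix, replace = TRUE), ,
                  drop = FALSE]
      tmpl <- rbind(tmpl[-drop, , drop = FALSE], add)
    }
  }
  # rigid jitter path: knots every 200 ms, linear interpolation
  n_knots <- dur_s * 5 + 1
  kx <- round(runif(n_knots, -cfg$jitter_px, cfg$jitter_px))
  ky <- round(runif(n_knots, -cfg$jitter_px, cfg$jitter_px))
  n_sig <- stats::rpois(1L, cfg$dvs_rate_hz * dur_s)
  n_noise <- stats::rpois(1L, cfg$dvs_noise_rate_hz * dur_s)
  t_sig <- sort(runif(n_sig, 0, dur_s * 1e6))
  knot_pos <- t_sig / (0.2 * 1e6)                  # in knot units
  i0 <- pmin(floor(knot_pos), n_knots - 2L)
  fr <- knot_pos - i0
  ox <- kx[i0 + 1L] * (1 - fr) + kx[i0 + 2L] * fr
  oy <- ky[i0 + 1L] * (1 - fr) + ky[i0 + 2L] * fr
  vx <- kx[i0 + 2L] - kx[i0 + 1L]                  # motion sign along path
  vy <- ky[i0 + 2L] - ky[i0 + 1L]
  pick <- sample.int(nrow(tmpl), n_sig, replace = TRUE)
  x <- pmin(pmax(tmpl[pick, 1L] + round(ox), 0L), 127L)
  y <- pmin(pmax(tmpl[pick, 2L] + round(oy), 0L), 127L)
  p <- as.integer(vx + vy > 0)
  flip <- runif(n_sig) < 0.1
  p[flip] <- 1L - p[flip]
  t_noise <- runif(n_noise, 0, dur_s * 1e6)
  t_all <- c(t_sig, t_noise)
  ord <- order(t_all)
  event_stream(t_all[ord],
               c(x, sample(0:127, n_noise, TRUE))[ord],
               c(y, sample(0:127, n_noise, TRUE))[ord],
               c(p, rbinom(n_noise, 1L, 0.5))[ord],
               width = 128L, height = 128L)
}

#' Generate a seeded synthetic two-modality gesture dataset
#'
#' Produces one 2 s recording per (subject, session, repetition, gesture)
#' cell of the manifest, deterministic given the seed, with balanced
#' labels. Use [chunk_dataset()] to cut the recordings into 200 ms
#' [gesture_sample()]s.
#'
#' @param cfg a [synth_config()].
#' @return list `(recordings, manifest, cfg)`; `recordings` is the input
#'   expected by [chunk_dataset()].
#' @export
generate_dataset <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  m <- cfg$manifest
  recs <- vector("list", m$n_subjects * m$n_sessions * m$n_repetitions *
                   m$n_gestures)
  pos <- 0L
  for (su in seq_len(m$n_subjects)) {
    gain <- runif(8, 0.85, 1.15)                   # per-subject electrode gain
    for (se in seq_len(m$n_sessions)) {
      rot <- runif(1, -cfg$emg_rotation, cfg$emg_rotation)
      for (re in seq_len(m$n_repetitions)) {
        for (g in seq_len(m$n_gestures)) {
          pos <- pos + 1L
          recs[[pos]] <- list(
            emg = gen_emg_recording(GESTURES[g], cfg, gain, rot),
            dvs = gen_dvs_recording(GESTURES[g], cfg),
            label = GESTURES[g], subject = su, session = se,
            repetition = re)
        }
      }
    }
  }
  list(recordings = recs, manifest = m, cfg = cfg)
}

#' Generate a linearly separable rate-coded toy spike dataset
#'
#' Each class activates a disjoint set of input channels (Bernoulli spikes
#' at a high rate on its own channels, a low noise rate elsewhere), so a
#' linear readout of spike counts separates the classes by construction.
#' Used as the training sanity benchmark for the surrogate-gradient
#' trainer.
#'
#' @param n_classes number of classes (channels are split evenly).
#' @param n_channels input channels.
#' @param n_per_class samples per class.
#' @param ticks raster length in ticks.
#' @param rate_hi,rate_lo per-tick spike probability on active / inactive
#'   channels.
#' @param seed RNG seed.
#' @return list `(rasters, labels, active_sets)`.
#' @export
generate_separable_toy <- function(n_classes = 2L, n_channels = 10L,
                                   n_per_class = 30L, ticks = 50L,
                                   rate_hi = 0.4, rate_lo = 0.02,
                                   seed = 1L) {
  set.seed(seed)
  per <- n_channels %/% n_classes
  active <- lapply(seq_len(n_classes), function(k)
    ((k - 1L) * per + 1L):(k * per))
  n <- n_classes * n_per_class
  labels <- rep(seq_len(n_classes), each = n_per_class)
  ord <- sample.int(n)
  labels <- labels[ord]
  rasters <- lapply(labels, function(k) {
    pr <- matrix(rate_lo, n_channels, ticks)
    pr[active[[k]], ] <- rate_hi
    spike_raster(matrix(rbinom(length(pr), 1L, as.vector(pr)),
                        n_channels, ticks),
                 layout = "rate-coded toy channels")
  })
  list(rasters = rasters, labels = labels, active_sets = active)
}

#' Synthesize gray-scale APS-like frames for a gesture
#'
#' Conventional-camera stand-in for the baseline path: the gesture template
#' rendered dark on a light background under the same rigid jitter model,
#' at a fixed frame rate (20 fps by default, i.e. the first frame is
#' available only 50 ms into the stimulus).
#'
#' @param gesture one of [GESTURES].
#' @param duration_ms stimulus duration.
#' @param fps frame rate.
#' @param jitter_px jitter amplitude.
#' @param seed RNG seed.
#' @return list with `frames` (list of 128x128 matrices in `[0, 1]`) and
#'   `frame_period_ms`.
#' @export
synth_aps_frames <- function(gesture, duration_ms = 200, fps = 20,
                             jitter_px = 5L, seed = 1L) {
  set.seed(seed)
  period <- 1000 / fps
  n_frames <- floor(duration_ms / period)
  tmpl <- gesture_template(gesture)
  frames <- lapply(seq_len(max(n_frames, 0L)), function(i) {
    f <- matrix(0.9, 128, 128)
    ox <- round(runif(1, -jitter_px, jitter_px))
    oy <- round(runif(1, -jitter_px, jitter_px))
    xs <- pmin(pmax(tmpl[, 1L] + ox, 0L), 127L)
    ys <- pmin(pmax(tmpl[, 2L] + oy, 0L), 127L)
    f[cbind(ys + 1L, xs + 1L)] <- 0.2
    f + matrix(rnorm(128 * 128, sd = 0.03), 128, 128)
  })
  list(frames = frames, frame_period_ms = period)
}
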