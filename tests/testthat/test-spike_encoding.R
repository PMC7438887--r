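test_that("delta modulation config validates", {
  expect_error(delta_mod_config(0), "threshold")
  expect_error(delta_mod_config(0.05, 0), "interpolation_factor")
  cfg <- delta_mod_config()
  expect_equal(cfg$threshold, 0.05)
  expect_equal(cfg$interpolation_factor, 3500L)
})

test_that("constant channels emit no spikes; single sample is legal", {
  rec <- emg_recording(matrix(200, 2, 40))
  tr <- delta_modulate(rec, delta_mod_config(0.05, 50))
  expect_equal(lengths(tr$up), c(0L, 0L))
  expect_equal(lengths(tr$down), c(0L, 0L))

  one <- delta_modulate(emg_recording(matrix(77, 1, 1)), delta_mod_config())
  expect_length(one$up[[1]], 0L)
  expect_length(one$down[[1]], 0L)
  expect_error(delta_modulate(emg_recording(matrix(numeric(), 1, 0))),
               "empty")
})

test_that("a full-range ramp emits floor(range/delta) UP spikes", {
  enc <- delta_encode(seq(0, 1, length.out = 40), 200,
                      delta_mod_config(0.05, 200))
  expect_length(enc$up, 20L)
  expect_length(enc$down, 0L)
  # down-ramp mirror
  enc2 <- delta_encode(seq(1, 0, length.out = 40), 200,
                       delta_mod_config(0.05, 200))
  expect_length(enc2$down, 20L)
  expect_length(enc2$up, 0L)
})

test_that("the encoder matches the plain-R tracking oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- cumsum(rnorm(30, sd = 0.04))
    o <- oracle_delta_mod(x, 200, 25, 0.05)
    e <- delta_encode(x, 200, delta_mod_config(0.05, 25))
    expect_equal(e$up, o$up)
    expect_equal(e$down, o$down)
  }
})

test_that("reconstruction follows the spike-count formula", {
  # 3 UP then 1 DOWN at delta = 0.05 from x(0) = 0 ends at 0.10
  tr <- structure(list(up = list(c(10, 20, 30)), down = list(50), x0 = 0,
                       channels = 1L, cfg = delta_mod_config(0.05, 1)),
                  class = "spike_train_pair")
  r <- reconstruct(tr, at = c(0, 15, 35, 60))
  expect_equal(as.numeric(r), c(0, 0.05, 0.15, 0.10))
  # empty trains reconstruct the constant x(0)
  tr0 <- structure(list(up = list(numeric(0)), down = list(numeric(0)),
                        x0 = 0.3, channels = 1L,
                        cfg = delta_mod_config(0.05, 1)),
                   class = "spike_train_pair")
  expect_equal(as.numeric(reconstruct(tr0, at = c(0, 100))), c(0.3, 0.3))
})

test_that("reconstruction error is bounded by delta + one interpolation step", {
  delta <- 0.05
  for (seed in 1:20) {
    set.seed(seed)
    x <- cumsum(rnorm(40, sd = 0.05))
    o <- oracle_delta_mod(x, 200, 30, delta)
    tr <- structure(list(up = list(o$up), down = list(o$down), x0 = x[1],
                         channels = 1L, cfg = delta_mod_config(delta, 30)),
                    class = "spike_train_pair")
    r <- reconstruct(tr, at = o$interp_t_us)
    step_max <- max(abs(diff(o$interp_signal)))
    expect_lte(max(abs(r[1, ] - o$interp_signal)), delta + step_max + 1e-9)
  }
})

test_that("encoding is per-channel independent under permutation", {
  set.seed(42)
  m <- matrix(sample(0:255, 4 * 40, TRUE), 4, 40)
  cfg <- delta_mod_config(0.05, 40)
  tr <- delta_modulate(emg_recording(m), cfg)
  perm <- c(3L, 1L, 4L, 2L)
  trp <- delta_modulate(emg_recording(m[perm, ]), cfg)
  expect_equal(trp$up, tr$up[perm])
  expect_equal(trp$down, tr$down[perm])
})

test_that("crop centers on the event median and clamps in-sensor", {
  # all events at one pixel: window centered there
  ev <- event_stream(rep(1:5, each = 1), rep(64L, 5), rep(32L, 5),
                     rep(1L, 5))
  cr <- crop_events(ev, 40L)
  expect_equal(n_events(cr), 5L)
  expect_equal(unique(cr$x), 20L)   # 64 - (64 - 20)
  expect_equal(unique(cr$y), 20L)
  # cluster near the corner: window clamps, events survive
  ev2 <- event_stream(1:5, c(0L, 1L, 0L, 2L, 1L), c(0L, 0L, 1L, 1L, 2L),
                      rep(0L, 5))
  cr2 <- crop_events(ev2, 40L)
  expect_equal(n_events(cr2), 5L)
  expect_true(all(cr2$x >= 0 & cr2$x < 40))
  # empty stream: empty crop at sensor center
  cr3 <- crop_events(event_stream(), 40L)
  expect_equal(n_events(cr3), 0L)
  expect_equal(c(cr3$width, cr3$height), c(40L, 40L))
})

test_that("uniform events survive cropping at about (40/128)^2", {
  set.seed(99)
  n <- 20000L
  ev <- event_stream(sort(runif(n, 0, 2e5)), sample(0:127, n, TRUE),
                     sample(0:127, n, TRUE), rbinom(n, 1, 0.5))
  cr <- crop_events(ev, 40L)
  frac <- n_events(cr) / n
  expect_lt(abs(frac - (40 / 128)^2), 0.01)
})

test_that("quad subsampling partitions events by parity", {
  # single event at (3, 5): phase (1, 1) -> stream k = 3 (position 4)
  ev <- event_stream(10, 3L, 5L, 1L, width = 40L, height = 40L)
  qs <- subsample_quad(ev)
  expect_equal(vapply(qs, n_events, 0L), c(0L, 0L, 0L, 1L))
  expect_equal(c(qs[[4]]$x, qs[[4]]$y), c(1L, 2L))

  # checkerboard of ON events on even (x+y): streams (0,0) and (1,1) only
  grid <- expand.grid(x = 0:39, y = 0:39)
  grid <- grid[(grid$x + grid$y) %% 2L == 0L, ]
  evc <- event_stream(seq_len(nrow(grid)), grid$x, grid$y,
                      rep(1L, nrow(grid)), width = 40L, height = 40L)
  qc <- subsample_quad(evc)
  expect_equal(vapply(qc, n_events, 0L)[c(2, 3)], c(0L, 0L))
  expect_equal(sum(vapply(qc, n_events, 0L)), n_events(evc))

  # random streams: always a partition
  set.seed(7)
  n <- 500L
  evr <- event_stream(sort(runif(n, 0, 1e5)), sample(0:39, n, TRUE),
                      sample(0:39, n, TRUE), rbinom(n, 1, .5),
                      width = 40L, height = 40L)
  qr <- subsample_quad(evr)
  expect_equal(sum(vapply(qr, n_events, 0L)), n)
  expect_error(subsample_quad(event_stream(width = 41L, height = 40L)),
               "even")
})

test_that("rasterization conserves in-window spikes and drops the rest", {
  # one spike at 0.4 ms lands in tick 0; 200 ms / 1 ms = 200 ticks
  ev <- event_stream(400, 0L, 0L, 1L, width = 2L, height = 2L)
  r <- rasterize(ev, tick = 1, duration_ms = 200)
  expect_equal(ncol(r$counts), 200L)
  expect_equal(r$counts[1, 1], 1L)       # ON plane first, pixel (0,0)
  expect_equal(sum(r$counts), 1)

  set.seed(3)
  n <- 300L
  t_us <- sort(runif(n, 0, 250 * 1000))  # some beyond the 200 ms window
  evr <- event_stream(t_us, sample(0:1, n, TRUE), sample(0:1, n, TRUE),
                      rbinom(n, 1, .5), width = 2L, height = 2L)
  expect_message(r2 <- rasterize(evr, 1, 200), "dropped")
  expect_equal(sum(r2$counts), sum(t_us < 200 * 1000))

  # merged polarity halves the channel count, conserves counts
  r3 <- suppressMessages(rasterize(evr, 1, 200, merge_polarity = TRUE))
  expect_equal(nrow(r3$counts), 4L)
  expect_equal(sum(r3$counts), sum(r2$counts))

  # spike train pair layout: 2 channels x {UP, DOWN} interleaved
  tr <- structure(list(up = list(c(500, 1500), numeric(0)),
                       down = list(numeric(0), 2500), x0 = c(0, 0),
                       channels = 2L, cfg = delta_mod_config()),
                  class = "spike_train_pair")
  r4 <- rasterize(tr, tick = 1, duration_ms = 10)
  expect_equal(nrow(r4$counts), 4L)
  expect_equal(which(r4$counts[1, ] > 0), c(1L, 2L))  # ch1 UP
  expect_equal(which(r4$counts[4, ] > 0), 3L)          # ch2 DOWN
  expect_equal(sum(r4$counts), 3)
})

test_that("spike rasters reject negative or fractional counts", {
  expect_error(spike_raster(matrix(-1, 1, 1)), "non-negative")
  expect_error(spike_raster(matrix(0.5, 1, 1)), "non-negative")
})
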