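test_that("cuba_step implements the exact discrete dynamics", {
  # decay 1024: v = 1000 * (4096 - 1024)/4096 = 750 after one silent tick
  st <- cuba_init(1, v0 = 1000)
  cfg <- neuron_config(1024, 1024, threshold = 2000)
  r <- cuba_step(st, 0, cfg)
  expect_identical(r$state$v, 750)
  expect_false(any(r$spikes))

  # voltage_decay = 4096: v depends only on the current tick's current
  cfg_full <- neuron_config(0, 4096, threshold = 10)
  st <- cuba_init(1, v0 = 5)
  r <- cuba_step(st, 3, cfg_full)
  expect_equal(r$state$v, 3)

  # below-threshold voltage decays monotonically toward 0, never spikes
  st <- cuba_init(1, v0 = 0.9)
  cfg2 <- neuron_config(4096, 512, threshold = 1)
  vs <- numeric(20)
  for (t in 1:20) {
    r <- cuba_step(st, 0, cfg2)
    st <- r$state
    vs[t] <- st$v
    expect_false(any(r$spikes))
  }
  expect_true(all(diff(c(0.9, vs)) <= 0))
  expect_gte(min(vs), 0)

  # reset to zero on spike, refractory blocks integration
  cfg3 <- neuron_config(4096, 0, threshold = 1, refractory = 2L)
  st <- cuba_init(1)
  r <- cuba_step(st, 5, cfg3)
  expect_true(r$spikes)
  expect_equal(r$state$v, 0)
  r2 <- cuba_step(r$state, 5, cfg3)
  expect_false(r2$spikes)
})

test_that("neuron and quant configs validate their ranges", {
  expect_error(neuron_config(5000), "\\[0, 4096\\]")
  expect_error(neuron_config(threshold = 0), "threshold")
  expect_error(quant_spec("int3", scale = 0), "scale")
  expect_error(layer_dense(2, delays = matrix(64, 1, 2)), "\\[0, 63\\]")
})

test_that("quantize projects onto the representable sets", {
  q3 <- quant_spec("int3", scale = 0.5)
  expect_equal(quantize(c(-10, -0.6, 0.2, 10), q3),
               c(-2, -0.5, 0, 1.5))
  expect_true(is_quantized(quantize(rnorm(100), q3), q3))
  qb <- quant_spec("binary")
  expect_equal(quantize(c(-0.2, 0, 3), qb), c(-1, 1, 1))
  q8 <- quant_spec("int8", scale = 1)
  expect_equal(quantize(c(-200, 0.4, 200), q8), c(-128, 0, 127))
  expect_false(is_quantized(0.3, q8))
  expect_true(is_quantized(NULL, q8))
})

test_that("network_spec validates shapes and chip precision", {
  expect_error(network_spec("bad", list(layer_dense(
    3, weights = matrix(0, 5, 3))), input_shape = 4),
    "shape mismatch at layer 1")
  expect_error(network_spec("bad", list(layer_pool()), input_shape = 16),
               "layer 1")
  expect_error(network_spec("bad", list(layer_dense(
    3, quant = quant_spec("float"))), input_shape = 4,
    chip_model = "odin"),
    "int3")
  # reference topologies compose
  expect_equal(spec_odin_emg()$output_shapes[[2]], 5L)
  cnn <- spec_loihi_dvs_cnn()
  expect_equal(cnn$output_shapes[[5]], c(32L, 10L, 10L))
  expect_equal(cnn$output_shapes[[6]], 3200L)
})

test_that("all-zero input with positive thresholds yields class 1", {
  spec <- init_network(network_spec("z", list(
    layer_dense(3, neuron = neuron_config(threshold = 1)),
    layer_dense(5, neuron = neuron_config(threshold = 1))),
    input_shape = 4), seed = 1)
  r <- run_network(spec, spike_raster(matrix(0L, 4, 20)), extra_ticks = 2)
  expect_equal(sum(r$counts), 0)
  expect_equal(r$decision, 1L)
})

test_that("an identity-like single-synapse net passes spikes through", {
  for (d in c(0L, 3L)) {
    spec <- network_spec("id", list(layer_dense(
      1, weights = matrix(100, 1, 1), delays = matrix(d, 1, 1),
      neuron = neuron_config(4096, 4096, threshold = 1))),
      input_shape = 1)
    x <- matrix(c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L, 0L, 0L), 1, 10)
    r <- run_network(spec, spike_raster(x), extra_ticks = 1L + d)
    expect_equal(sum(r$counts), sum(x))
    # delayed by 1 + d ticks
    expect_equal(which(r$trace[1, ] > 0), which(x[1, ] > 0) + 1L + d)
  }
})

test_that("the simulator matches the naive event-driven oracle exactly", {
  for (seed in 1:12) {
    spec <- random_dense_spec(seed, n_in = 4L, layers = c(6L, 3L),
                              with_delays = seed %% 2L == 0L)
    ras <- random_raster(seed + 100L)
    r <- run_network(spec, ras, extra_ticks = 5L)
    o <- oracle_run_dense(spec, ras, extra_ticks = 5L)
    expect_identical(r$trace, o$trace)
    expect_equal(r$counts, o$counts)
    expect_equal(r$final_v, o$final_v)
    expect_equal(r$spike_totals, o$spike_totals)
  }
})

test_that("simulation is deterministic and monotone in input spikes", {
  spec <- random_dense_spec(5)
  ras <- random_raster(50)
  r1 <- run_network(spec, ras, extra_ticks = 3L)
  r2 <- run_network(spec, ras, extra_ticks = 3L)
  expect_identical(r1, r2)

  # excitatory-only single layer: adding spikes never reduces output
  set.seed(8)
  W <- matrix(runif(4 * 3, 0.1, 1), 4, 3)
  spec_e <- network_spec("exc", list(layer_dense(
    3, weights = W, neuron = neuron_config(1024, 1024, 1))),
    input_shape = 4)
  base <- matrix(rbinom(4 * 30, 1L, 0.2), 4, 30)
  r_base <- run_network(spec_e, spike_raster(base), extra_ticks = 2L)
  for (k in 1:5) {
    extra <- base
    zero <- which(extra == 0L)
    extra[sample(zero, 8)] <- 1L
    r_more <- run_network(spec_e, spike_raster(extra), extra_ticks = 2L)
    expect_gte(sum(r_more$counts), sum(r_base$counts))
  }
})

test_that("batched forward equals the per-sample simulator", {
  spec <- random_dense_spec(21, n_in = 5L, layers = c(7L, 4L))
  rasters <- lapply(1:6, function(s) random_raster(s, n_ch = 5L))
  fb <- snn_forward_batch(spec, stack_rasters(rasters), extra_ticks = 3L,
                          batch = 4L)
  for (i in seq_along(rasters)) {
    r <- run_network(spec, rasters[[i]], extra_ticks = 3L)
    expect_equal(fb$counts[i, ], unname(r$counts))
    expect_equal(fb$decisions[i], r$decision)
    expect_equal(fb$final_v[i, ], r$final_v)
  }
  expect_error(snn_forward_batch(random_dense_spec(1, with_delays = TRUE),
                                 array(0, c(1, 4, 5))),
               "no-delay")
})

test_that("conv and pool layers follow their definitions", {
  # single ON event through a known 3x3 kernel: membrane pattern = kernel
  K <- array(0, c(3, 3, 1, 1))
  K[, , 1, 1] <- matrix(1:9 / 10, 3, 3)
  spec <- network_spec("c", list(layer_conv(
    1L, 3L, weights = K, neuron = neuron_config(4096, 4096, 0.45))),
    input_shape = c(1L, 5L, 5L))
  x <- matrix(0L, 25, 3)
  x[13, 1] <- 1L                       # center pixel (3,3), tick 1
  r <- run_network(spec, spike_raster(x), extra_ticks = 1L)
  out <- array(r$trace[, 2], c(1, 5, 5))
  # threshold 0.45: kernel entries 0.5..0.9 spike (5 of 9 positions)
  expect_equal(sum(out), 5)
  # impulse response of a correlation layer: the kernel appears flipped
  ref <- matrix(0, 5, 5)
  ref[2:4, 2:4] <- (matrix(1:9 / 10, 3, 3) >= 0.45)[3:1, 3:1]
  expect_equal(array(out[1, , ], c(5, 5)), ref + 0)

  # pooling: OR over 2x2 blocks, instantaneous
  specp <- network_spec("p", list(layer_pool()), input_shape = c(1L, 4L, 4L))
  xp <- matrix(0L, 16, 2)
  xp[c(1, 2, 6), 1] <- 1L   # three spikes in the top-left 2x2 block
  rp <- run_network(specp, spike_raster(xp))
  expect_equal(sum(rp$trace[, 1]), 1)  # a single pooled indicator
})

test_that("fusion specs concatenate penultimate layers", {
  a <- init_network(spec_odin_emg(), seed = 1)
  b <- init_network(spec_morphic_dvs(), seed = 2)
  b$mode <- "concat_hidden"
  f <- build_fusion(a, b, output_quant = quant_spec("int3"))
  expect_equal(f$input_width, 1070L)

  mlp <- init_network(spec_loihi_emg_mlp(), seed = 3)
  cnn <- spec_loihi_dvs_cnn()
  expect_error(build_fusion(mlp, cnn), "trained")
  # loihi pair: 128 + 512 = 640 (CNN init is slow; fake a trained marker
  # by checking the declared penultimate widths instead)
  expect_equal(spikefuse:::penultimate_width(mlp), 128L)
  expect_equal(spikefuse:::penultimate_width(cnn), 512L)

  # fusing a net with itself doubles the width
  f2 <- build_fusion(a, a)
  expect_equal(f2$input_width, 2L * 230L)
})

test_that("subMLP ensembles sum outputs or concatenate hidden layers", {
  set.seed(4)
  mk_branch <- function(W1, W2) network_spec("b", list(
    layer_dense(3, weights = W1, neuron = neuron_config(4096, 0, 1)),
    layer_dense(2, weights = W2, neuron = neuron_config(4096, 0, 1))),
    input_shape = 2)
  W1 <- matrix(runif(6, 0.5, 1), 2, 3)
  W2 <- matrix(runif(6, 0.5, 1), 3, 2)
  branches <- lapply(1:4, function(k) mk_branch(W1, W2))
  ens <- submlp_ensemble(branches, mode = "sum_outputs")
  ras <- random_raster(9, n_ch = 2L, ticks = 15L)
  streams <- lapply(1:4, function(k) ras)
  r_ens <- run_network(ens, streams, extra_ticks = 2L)
  r_one <- run_network(branches[[1]], ras, extra_ticks = 2L)
  # identical streams + identical weights: ensemble = 4 x single branch
  expect_equal(r_ens$counts, 4 * r_one$counts)

  # one active branch only: ensemble equals that branch
  silent <- spike_raster(matrix(0L, 2, 15))
  streams2 <- list(ras, silent, silent, silent)
  r_ens2 <- run_network(ens, streams2, extra_ticks = 2L)
  expect_equal(r_ens2$counts, r_one$counts)

  # concat_hidden exports 4 x hidden units
  ens$mode <- "concat_hidden"
  rc <- run_network(ens, streams, extra_ticks = 2L)
  expect_equal(nrow(rc$hidden_trace), 12L)
  expect_length(submlp_ensemble(branches)$branches, 4L)
  expect_error(submlp_ensemble(branches[1:3]), "4 branch")
})

test_that("specs serialize to JSON and back without loss", {
  f <- withr::local_tempfile(fileext = ".json")
  spec <- random_dense_spec(31, with_delays = TRUE)
  spec$layers[[1]]$quant <- quant_spec("int8", scale = 0.25)
  spec$layers[[1]]$weights <- quantize(spec$layers[[1]]$weights,
                                       spec$layers[[1]]$quant)
  spec_to_json(spec, f)
  back <- spec_from_json(f)
  expect_equal(back$layers[[1]]$weights, spec$layers[[1]]$weights)
  expect_equal(back$layers[[1]]$delays, spec$layers[[1]]$delays)
  expect_equal(back$layers[[2]]$neuron, spec$layers[[2]]$neuron)
  expect_true(check_quantized(back))   # quantization closure on round-trip
  ras <- random_raster(77)
  expect_equal(run_network(back, ras, 3L)$counts,
               run_network(spec, ras, 3L)$counts)
})

test_that("weight hashes detect any upstream change", {
  a <- init_network(spec_odin_emg(), seed = 1)
  h <- weight_hash(a)
  expect_identical(weight_hash(a), h)
  a$layers[[1]]$weights[1, 1] <- a$layers[[1]]$weights[1, 1] + 1
  expect_false(identical(weight_hash(a), h))
})
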