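test_that("the surrogate backward pass matches finite differences of the
           smoothed loss", {
  set.seed(5)
  # 3-neuron net: 1 input channel -> 1 hidden -> 2 outputs
  spec <- network_spec("fd", list(
    layer_dense(1, weights = matrix(0.8, 1, 1),
                neuron = neuron_config(1024, 512, 0.7),
                quant = quant_spec("float")),
    layer_dense(2, weights = matrix(c(0.5, -0.4), 1, 2),
                neuron = neuron_config(2048, 1024, 0.6),
                quant = quant_spec("float"))),
    input_shape = 1)
  X <- array(rbinom(2 * 1 * 15, 1, 0.5), c(2, 1, 15))
  y <- c(1L, 2L)
  g <- snn_gradient(spec, X, y, width = 0.6, smooth = TRUE)
  h <- 1e-5
  for (li in 1:2) {
    W <- spec$layers[[li]]$weights
    for (j in seq_along(W)) {
      sp <- spec
      sp$layers[[li]]$weights[j] <- W[j] + h
      lp <- snn_gradient(sp, X, y, width = 0.6, smooth = TRUE)$loss
      sp$layers[[li]]$weights[j] <- W[j] - h
      lm <- snn_gradient(sp, X, y, width = 0.6, smooth = TRUE)$loss
      expect_lt(abs((lp - lm) / (2 * h) - g$grads[[li]][j]), 1e-4)
    }
  }
})

test_that("zero learning rate leaves weights unchanged", {
  toy <- generate_separable_toy(2, 6, n_per_class = 5, ticks = 20, seed = 2)
  spec <- init_network(network_spec("t", list(
    layer_dense(4, neuron = neuron_config(1024, 1024, 1),
                quant = quant_spec("int8")),
    layer_dense(2, neuron = neuron_config(1024, 1024, 1),
                quant = quant_spec("int8"))),
    input_shape = 6, chip_model = "loihi"), seed = 1)
  w_before <- lapply(spec$layers, function(l) {
    w <- l$weights
    attributes(w) <- attributes(w)["dim"]
    w
  })
  tr <- train_surrogate(spec, list(rasters = toy$rasters,
                                   labels = toy$labels),
                        train_config(epochs = 2, lr = 0, seed = 3))
  w_after <- lapply(tr$layers, function(l) {
    w <- l$weights
    attributes(w) <- attributes(w)["dim"]
    w
  })
  expect_equal(w_after, w_before)
})

test_that("surrogate training learns the separable toy problem and stays
           quantization-closed at every step", {
  toy <- generate_separable_toy(2, 10, n_per_class = 20, ticks = 50,
                                seed = 3)
  closed <- TRUE
  hook <- function(spec, step) closed <<- closed && check_quantized(spec)
  spec <- spec_loihi_emg_mlp()
  spec$layers <- list(                 # scaled-down 2-layer loihi net
    layer_dense(16, neuron = neuron_config(1024, 1024, 1),
                quant = quant_spec("int8")),
    layer_dense(2, neuron = neuron_config(1024, 1024, 1),
                quant = quant_spec("int8")))
  spec <- network_spec("toy-loihi", spec$layers, input_shape = 10,
                       chip_model = "loihi")
  tr <- train_surrogate(spec, list(rasters = toy$rasters,
                                   labels = toy$labels),
                        train_config(epochs = 8, lr = 0.02, seed = 1,
                                     step_hook = hook))
  hist <- attr(tr, "history")
  expect_gte(tail(hist$accuracy, 1), 0.95)
  expect_true(closed)
  expect_true(check_quantized(tr))
  # determinism: same seed, same final weights
  tr2 <- train_surrogate(spec, list(rasters = toy$rasters,
                                    labels = toy$labels),
                         train_config(epochs = 8, lr = 0.02, seed = 1))
  expect_identical(lapply(tr$layers, `[[`, "weights"),
                   lapply(tr2$layers, `[[`, "weights"))
})

test_that("the 16-128d-128d-5 topology instantiates with trainable delays", {
  spec <- init_network(spec_loihi_emg_mlp(), seed = 1, delay_layers = 1:2)
  expect_equal(vapply(spec$layers, function(l) l$units, 0L),
               c(128L, 128L, 5L))
  expect_false(is.null(spec$layers[[1]]$delays))
  expect_true(all(spec$layers[[1]]$delays >= 0 &
                    spec$layers[[1]]$delays <= 63))
  expect_true(check_quantized(spec))

  # delays remain integers in [0, 63] after training
  toy <- generate_separable_toy(5, 16, n_per_class = 4, ticks = 20, seed = 4)
  tr <- train_surrogate(init_network(spec_loihi_emg_mlp(), seed = 1,
                                     delay_layers = 1:2),
                        list(rasters = toy$rasters, labels = toy$labels),
                        train_config(epochs = 1, lr = 0.01, seed = 1,
                                     train_delays = TRUE, batch_size = 10))
  for (l in tr$layers[1:2]) {
    expect_true(all(l$delays == round(l$delays)))
    expect_true(all(l$delays >= 0 & l$delays <= 63))
  }
})

test_that("quantization-aware ANN training learns above chance and stays
           in the representable set", {
  set.seed(6)
  toyc <- generate_separable_toy(5, 16, n_per_class = 30, ticks = 50,
                                 seed = 5)
  x <- t(vapply(toyc$rasters, function(r) rowSums(r$counts), numeric(16)))
  dat <- list(x = x, y = toyc$labels)
  ann <- train_quantized_ann(spec_odin_emg(), dat,
                             train_config(epochs = 10, seed = 1))
  expect_gt(ann_accuracy(ann, dat), 0.5)          # chance = 0.2
  expect_true(check_quantized(ann))
  expect_equal(ann$layers[[1]]$quant$kind, "int3")

  # binary-weight subMLP branch
  set.seed(7)
  xb <- matrix(rpois(120 * 400, 2), 120, 400)
  yb <- rep(1:5, 24)
  for (k in 1:5) xb[yb == k, (k - 1) * 80 + 1:80] <-
    xb[yb == k, (k - 1) * 80 + 1:80] + 4
  annb <- train_quantized_ann(spec_morphic_branch(),
                              list(x = xb, y = yb),
                              train_config(epochs = 10, seed = 2))
  expect_gt(ann_accuracy(annb, list(x = xb, y = yb)), 0.5)
  expect_true(all(annb$layers[[1]]$weights %in% c(-1, 1)))
})

test_that("ANN-to-SNN mapping preserves weights and picks live thresholds", {
  # trivial 1-1 net: weight 1, threshold 1 -> rate identity
  spec <- network_spec("one", list(layer_dense(
    1, weights = matrix(1, 1, 1),
    neuron = neuron_config(4096, 0, 1))), input_shape = 1)
  x <- matrix(rep(c(1L, 0L), 10), 1, 20)
  r <- run_network(spec, spike_raster(x), extra_ticks = 1L)
  expect_equal(sum(r$counts), sum(x))

  toyc <- generate_separable_toy(5, 16, n_per_class = 20, ticks = 50,
                                 seed = 8)
  x <- t(vapply(toyc$rasters, function(r) rowSums(r$counts), numeric(16)))
  dat <- list(x = x, y = toyc$labels)
  ann <- train_quantized_ann(spec_odin_emg(), dat,
                             train_config(epochs = 8, seed = 1))
  snn <- ann_to_snn(ann, threshold_search_spec(c(0.5, 1, 2)),
                    cal = dat, val = list(rasters = toyc$rasters,
                                          y = toyc$labels))
  # weights installed unchanged
  expect_identical(snn$layers[[1]]$weights, ann$layers[[1]]$weights)
  expect_gt(attr(snn, "hidden_rate"), 0)
  ev <- spikefuse:::snn_eval(snn, toyc$rasters, toyc$labels)
  expect_gt(ev$accuracy, 0.5)

  # SNN rates correlate positively with ANN activations, per layer
  fb <- snn_forward_batch(snn, stack_rasters(toyc$rasters))
  acts <- spikefuse:::ann_forward(ann, x)
  expect_gt(cor(as.vector(fb$hidden_counts), as.vector(pmax(acts[[1]], 0)),
                method = "spearman"), 0)
  expect_gt(cor(as.vector(fb$counts), as.vector(pmax(acts[[2]], 0)),
                method = "spearman"), 0)

  # thresholds far beyond the activations: silent at every grid point
  expect_error(ann_to_snn(ann, threshold_search_spec(c(1e6, 1e7)),
                          cal = dat, val = list(rasters = toyc$rasters,
                                                y = toyc$labels)),
               "grid")
})

test_that("fusion head retraining freezes the upstream networks", {
  set.seed(9)
  toyc <- generate_separable_toy(5, 16, n_per_class = 12, ticks = 40,
                                 seed = 9)
  x <- t(vapply(toyc$rasters, function(r) rowSums(r$counts), numeric(16)))
  dat <- list(x = x, y = toyc$labels)
  ann <- train_quantized_ann(spec_odin_emg(), dat,
                             train_config(epochs = 6, seed = 1))
  snn <- ann_to_snn(ann, threshold_search_spec(c(0.5, 1, 2)),
                    cal = dat, val = list(rasters = toyc$rasters,
                                          y = toyc$labels))
  fused <- build_fusion(snn, snn, output_quant = quant_spec("int3"))
  h_before <- weight_hash(spikefuse:::list_upstream(fused))
  H <- fusion_hidden_counts(fused, toyc$rasters, toyc$rasters)
  ft <- retrain_fusion_head(fused, list(hidden = H, y = toyc$labels),
                            train_config(epochs = 6, seed = 2))
  expect_identical(weight_hash(spikefuse:::list_upstream(ft)), h_before)
  expect_true(is_quantized(ft$head$weights, ft$head$quant))
  r <- run_network(ft, list(a = toyc$rasters[[1]], b = toyc$rasters[[1]]),
                   extra_ticks = 2L)
  expect_length(r$counts, 5L)
})

test_that("non-finite losses abort with diagnostics", {
  toy <- generate_separable_toy(2, 6, n_per_class = 4, ticks = 10, seed = 1)
  spec <- init_network(network_spec("t", list(
    layer_dense(2, neuron = neuron_config(1024, 1024, 1),
                quant = quant_spec("int8"))),
    input_shape = 6, chip_model = "loihi"), seed = 1)
  # blow up the weights so counts overflow the softmax
  spec$layers[[1]]$weights <- matrix(1e308, 6, 2)
  attr(spec$layers[[1]]$weights, "shadow") <- matrix(1e308, 6, 2)
  expect_error(train_surrogate(spec, list(rasters = toy$rasters,
                                          labels = toy$labels),
                               train_config(epochs = 1, seed = 1)),
               "non-finite")
})
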