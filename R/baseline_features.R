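## Traditional-ML baseline path: time-domain EMG features and the
## non-spiking twin topologies of the chip networks.

#' Mean absolute value of an EMG window
#'
#' `MAV = (1/T) * sum |x(t)|` over a window of T samples.
#' @param x numeric window (one channel).
#' @param T window length; must equal `length(x)`.
#' @export
mav <- function(x, T = length(x)) {
  if (length(x) == 0L) stop("empty window")
  if (length(x) != T) stop("window has ", length(x), " samples, expected ", T)
  mean(abs(x))
}

#' Root mean square of an EMG window
#'
#' `RMS = sqrt((1/T) * sum x(t)^2)`; always >= MAV (Cauchy-Schwarz).
#' @inheritParams mav
#' @export
rms <- function(x, T = length(x)) {
  if (length(x) == 0L) stop("empty window")
  if (length(x) != T) stop("window has ", length(x), " samples, expected ", T)
  sqrt(mean(x^2))
}

#' Per-window feature vector: MAV block then RMS block
#'
#' `E(n) = [MAV(x_1)..MAV(x_C), RMS(x_1)..RMS(x_C)]`, length 2C (16 for the
#' 8-channel armband), channel order preserved within each block.
#'
#' @param window channels x T numeric matrix (one 40-sample window = 200 ms
#'   at 200 Hz).
#' @param normalized compute on the encoder-normalized signal instead of
#'   raw unitless values (default FALSE: raw, as in conventional EMG
#'   pipelines).
#' @export
feature_vector <- function(window, normalized = FALSE) {
  if (!is.matrix(window) || ncol(window) == 0L) stop("empty window")
  if (normalized) window <- normalize_emg(window)
  c(apply(window, 1L, mav), apply(window, 1L, rms))
}

#' Sliding-window features over a recording
#'
#' Non-overlapping windows by default (stride = window), matching the
#' 10-chunks-per-2-s layout. Shifting the start by one window advances the
#' window index by one.
#'
#' @param rec an [emg_recording()].
#' @param window window length in samples (default 40 = 200 ms at 200 Hz).
#' @param stride window stride in samples (default `window`).
#' @param normalized see [feature_vector()].
#' @return windows x 2C feature matrix.
#' @export
emg_features <- function(rec, window = 40L, stride = window,
                         normalized = FALSE) {
  n <- ncol(rec$samples)
  starts <- seq(1L, n - window + 1L, by = stride)
  t(vapply(starts, function(s)
    feature_vector(rec$samples[, s:(s + window - 1L), drop = FALSE],
                   normalized = normalized),
    numeric(2L * nrow(rec$samples))))
}

#' Non-spiking baseline network topologies
#'
#' Float-precision (ReLU/softmax) twins of the chip networks: the EMG MLPs
#' 16-230-5 and 16-128-128-5 operating on MAV/RMS features, the four
#' 400-210-5 frame subMLPs on 40x40 sub-sampled gray-scale frames, and the
#' frame CNN mirroring the spiking CNN but with a single gray-scale input
#' channel (so the two differ in parameter count only in layer 1).
#'
#' @return named list of untrained `network_spec` /
#'   [submlp_ensemble()] objects.
#' @export
baseline_networks <- function() {
  fl <- quant_spec("float")
  relu <- neuron_config()  # neuron configs unused on the ANN path
  dense <- function(u) layer_dense(u, neuron = relu, quant = fl)
  list(
    emg_mlp_odin = network_spec(
      "baseline-emg-16-230-5", list(dense(230L), dense(5L)),
      input_shape = 16L),
    emg_mlp_loihi = network_spec(
      "baseline-emg-16-128-128-5",
      list(dense(128L), dense(128L), dense(5L)), input_shape = 16L),
    frame_submlp = submlp_ensemble(
      lapply(1:4, function(k)
        network_spec("baseline-frame-400-210-5",
                     list(dense(210L), dense(5L)), input_shape = 400L)),
      mode = "sum_outputs"),
    frame_cnn = network_spec(
      "baseline-frame-cnn",
      list(layer_conv(8L, 3L, neuron = relu, quant = fl),
           layer_pool(),
           layer_conv(16L, 3L, neuron = relu, quant = fl),
           layer_pool(),
           layer_conv(32L, 3L, neuron = relu, quant = fl),
           layer_flatten(),
           dense(512L), dense(5L)),
      input_shape = c(1L, 40L, 40L)))
}

#' Number of trainable weights of a spec (from shapes, trained or not)
#' @param spec a `network_spec` or `submlp_ensemble`.
#' @export
n_parameters <- function(spec) {
  if (inherits(spec, "submlp_ensemble"))
    return(sum(vapply(spec$branches, n_parameters, 0)))
  shapes <- c(list(spec$input_shape), spec$output_shapes)
  sum(vapply(seq_along(spec$layers), function(li) {
    l <- spec$layers[[li]]
    switch(l$kind,
           dense = prod(shapes[[li]]) * l$units,
           conv = l$kernel^2 * shapes[[li]][1] * l$filters,
           0)
  }, 0))
}
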