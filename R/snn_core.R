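## Discrete-time simulator for quantized spiking networks.
##
## Timing convention (fixed, shared with the training code and the test
## oracle): synaptic input crosses a dense/conv stage with one tick of
## transport latency plus the integer axonal delay d, i.e. a spike emitted
## by the presynaptic layer at tick t is integrated by the postsynaptic
## layer at tick t + 1 + d. Pooling and flatten stages are instantaneous
## reshapes of the same tick's spikes (they have no synapses).

DECAY_SCALE <- 4096

#' CUBA-LIF neuron configuration
#'
#' Current-based leaky integrate-and-fire dynamics on a 1 ms tick grid,
#' following the fixed-point convention of digital neuromorphic cores: each
#' tick the synaptic current and membrane voltage are scaled by
#' `(4096 - decay)/4096`. `decay = 0` means no leak, `decay = 4096` full
#' leak within one tick. Membrane resets to zero on spike.
#'
#' @param current_decay,voltage_decay per-tick decay parameters in
#'   `[0, 4096]`.
#' @param threshold firing threshold (membrane units), > 0.
#' @param refractory refractory period in ticks (default 0); while
#'   refractory the membrane is clamped to zero and cannot spike.
#' @export
neuron_config <- function(current_decay = 1024, voltage_decay = 1024,
                          threshold = 1, refractory = 0L) {
  if (current_decay < 0 || current_decay > DECAY_SCALE ||
      voltage_decay < 0 || voltage_decay > DECAY_SCALE)
    stop("decays must lie in [0, 4096]")
  if (threshold <= 0) stop("threshold must be > 0")
  structure(list(current_decay = current_decay,
                 voltage_decay = voltage_decay,
                 threshold = threshold,
                 refractory = as.integer(refractory)),
            class = "neuron_config")
}

#' One CUBA-LIF update step
#'
#' Applies the exact discrete dynamics to a population:
#' `i[t] = i[t-1]*(4096 - cd)/4096 + input`,
#' `v[t] = v[t-1]*(4096 - vd)/4096 + i[t]`,
#' spike iff `v[t] >= threshold`, after which `v` is reset to zero and the
#' neuron enters its refractory period (if configured).
#'
#' @param state list with numeric vectors `i`, `v` and integer `refrac`
#'   (remaining refractory ticks); use [cuba_init()] to create one.
#' @param input weighted synaptic input arriving this tick (numeric vector).
#' @param cfg a [neuron_config()].
#' @return list `(state = updated state, spikes = logical vector)`.
#' @export
cuba_step <- function(state, input, cfg) {
  ai <- (DECAY_SCALE - cfg$current_decay) / DECAY_SCALE
  av <- (DECAY_SCALE - cfg$voltage_decay) / DECAY_SCALE
  i <- state$i * ai + input
  v <- state$v * av + i
  refrac <- state$refrac
  blocked <- refrac > 0L
  v[blocked] <- 0
  spikes <- !blocked & v >= cfg$threshold
  v[spikes] <- 0
  refrac <- pmax(refrac - 1L, 0L)
  refrac[spikes] <- cfg$refractory
  list(state = list(i = i, v = v, refrac = refrac), spikes = spikes)
}

#' Initialize CUBA state for a population
#' @param n population size.
#' @param v0,i0 initial membrane voltage / synaptic current.
#' @export
cuba_init <- function(n, v0 = 0, i0 = 0) {
  list(i = rep(i0, n), v = rep(v0, n), refrac = rep(0L, n))
}

## ---------------------------------------------------------------------------
## Quantization
## ---------------------------------------------------------------------------

#' Weight quantization specification
#'
#' The representable sets mirror the modelled chips: `binary` is
#' `{-1, +1} * scale` (MorphIC), `int3` is signed 3-bit integers
#' `[-4, 3] * scale` (ODIN), `int8` is signed 8-bit `[-128, 127] * scale`
#' (Loihi), `float` is unconstrained.
#'
#' @param kind one of "float", "binary", "int3", "int8".
#' @param scale positive per-layer scale factor.
#' @export
quant_spec <- function(kind = c("float", "binary", "int3", "int8"),
                       scale = 1) {
  kind <- match.arg(kind)
  if (scale <= 0) stop("scale must be > 0")
  structure(list(kind = kind, scale = scale), class = "quant_spec")
}

quant_range <- function(kind) {
  switch(kind, int3 = c(-4, 3), int8 = c(-128, 127),
         stop("no integer range for kind ", kind))
}

#' Project weights onto a quantization spec's representable set
#' @param w numeric array of weights.
#' @param q a [quant_spec()].
#' @export
quantize <- function(w, q) {
  switch(q$kind,
         float = w,
         binary = ifelse(w >= 0, 1, -1) * q$scale,
         {
           r <- quant_range(q$kind)
           pmin(pmax(round(w / q$scale), r[1]), r[2]) * q$scale
         })
}

#' Test whether all weights lie in the representable set
#' @param w numeric array; @param q a [quant_spec()]; @param tol tolerance.
#' @export
is_quantized <- function(w, q, tol = 1e-9) {
  if (is.null(w)) return(TRUE)
  all(abs(w - quantize(w, q)) <= tol)
}

## ---------------------------------------------------------------------------
## Layers and network specs
## ---------------------------------------------------------------------------

#' Dense (fully connected) spiking layer
#'
#' @param units number of neurons.
#' @param weights optional in x units weight matrix (NULL = untrained).
#' @param delays optional in x units integer matrix of axonal delays in
#'   ticks, each in `[0, 63]` (6-bit range).
#' @param neuron a [neuron_config()].
#' @param quant a [quant_spec()].
#' @export
layer_dense <- function(units, weights = NULL, delays = NULL,
                        neuron = neuron_config(), quant = quant_spec()) {
  if (!is.null(delays)) {
    if (any(delays < 0 | delays > 63) || any(delays != round(delays)))
      stop("delays must be integers in [0, 63]")
  }
  structure(list(kind = "dense", units = as.integer(units),
                 weights = weights, delays = delays, neuron = neuron,
                 quant = quant),
            class = "snn_layer")
}

#' Convolutional spiking layer (square kernel, stride 1, zero 'same' padding)
#'
#' @param filters number of output channels.
#' @param kernel square kernel side length.
#' @param weights optional array `(kernel, kernel, in_channels, filters)`.
#' @param neuron a [neuron_config()]; @param quant a [quant_spec()].
#' @export
layer_conv <- function(filters, kernel = 3L, weights = NULL,
                       neuron = neuron_config(), quant = quant_spec()) {
  structure(list(kind = "conv", filters = as.integer(filters),
                 kernel = as.integer(kernel), weights = weights,
                 neuron = neuron, quant = quant),
            class = "snn_layer")
}

#' 2x2 max-pooling layer (logical OR over per-tick spike indicators)
#' @export
layer_pool <- function() {
  structure(list(kind = "pool", size = 2L), class = "snn_layer")
}

#' Flatten layer (reshape only, no latency)
#' @export
layer_flatten <- function() {
  structure(list(kind = "flatten"), class = "snn_layer")
}

CHIP_QUANT <- c(odin = "int3", morphic = "binary", loihi = "int8")

#' Assemble a layered spiking network
#'
#' Validates that layer shapes compose (an error names the offending layer)
#' and that the chip model's weight precision matches every synaptic
#' layer's quantization spec (odin -> int3, morphic -> binary,
#' loihi -> int8).
#'
#' @param name network name.
#' @param layers list of layers from [layer_dense()], [layer_conv()],
#'   [layer_pool()], [layer_flatten()].
#' @param input_shape integer vector: channel count for vector inputs, or
#'   `c(planes, height, width)` for image inputs.
#' @param chip_model one of "none", "odin", "morphic", "loihi".
#' @export
network_spec <- function(name, layers, input_shape,
                         chip_model = c("none", "odin", "morphic", "loihi")) {
  chip_model <- match.arg(chip_model)
  shape <- as.integer(input_shape)
  shapes <- vector("list", length(layers))
  for (li in seq_along(layers)) {
    l <- layers[[li]]
    shape <- switch(
      l$kind,
      dense = {
        n_in <- prod(shape)
        if (!is.null(l$weights) && !all(dim(l$weights) == c(n_in, l$units)))
          stop("shape mismatch at layer ", li, " ('", l$kind, "'): weights ",
               paste(dim(l$weights), collapse = "x"), " vs expected ",
               n_in, "x", l$units)
        l$units
      },
      conv = {
        if (length(shape) != 3L)
          stop("shape mismatch at layer ", li, ": conv needs (C,H,W) input")
        if (!is.null(l$weights) &&
            !all(dim(l$weights) == c(l$kernel, l$kernel, shape[1], l$filters)))
          stop("shape mismatch at layer ", li, ": conv weights")
        c(l$filters, shape[2], shape[3])
      },
      pool = {
        if (length(shape) != 3L || shape[2] %% 2L || shape[3] %% 2L)
          stop("shape mismatch at layer ", li, ": pool needs even (C,H,W)")
        c(shape[1], shape[2] %/% 2L, shape[3] %/% 2L)
      },
      flatten = prod(shape),
      stop("unknown layer kind at layer ", li))
    if (chip_model != "none" && l$kind %in% c("dense", "conv") &&
        l$quant$kind != CHIP_QUANT[[chip_model]])
      stop("chip model '", chip_model, "' requires ",
           CHIP_QUANT[[chip_model]], " weights at layer ", li)
    shapes[[li]] <- shape
  }
  structure(list(name = name, layers = layers,
                 input_shape = as.integer(input_shape),
                 output_shapes = shapes, chip_model = chip_model),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  dims <- vapply(x$output_shapes, function(s) paste(s, collapse = "x"), "")
  cat(sprintf("<network_spec> %s [%s]: %s -> %s\n", x$name, x$chip_model,
              paste(x$input_shape, collapse = "x"),
              paste(dims, collapse = " -> ")))
  invisible(x)
}

#' Is every synaptic layer of the spec trained (weights present)?
#' @param spec a `network_spec`.
#' @export
is_trained <- function(spec) {
  UseMethod("is_trained")
}

#' @export
is_trained.network_spec <- function(spec) {
  all(vapply(spec$layers, function(l)
    !(l$kind %in% c("dense", "conv")) || !is.null(l$weights), TRUE))
}

#' @export
is_trained.submlp_ensemble <- function(spec) {
  all(vapply(spec$branches, is_trained, TRUE))
}

#' Check quantization closure of a network
#'
#' TRUE iff every stored weight belongs to its layer's representable set.
#' @param spec a `network_spec` (or ensemble / fusion spec).
#' @export
check_quantized <- function(spec) {
  if (inherits(spec, "submlp_ensemble"))
    return(all(vapply(spec$branches, check_quantized, TRUE)))
  if (inherits(spec, "fusion_spec"))
    return(check_quantized(spec$net_a) && check_quantized(spec$net_b) &&
             is_quantized(spec$head$weights, spec$head$quant))
  all(vapply(spec$layers, function(l) {
    if (!(l$kind %in% c("dense", "conv"))) return(TRUE)
    is_quantized(l$weights, l$quant)
  }, TRUE))
}

#' Deterministic digest of all synaptic weights (for freeze contracts)
#' @param spec a network, ensemble or fusion spec.
#' @export
weight_hash <- function(spec) {
  rlang::hash(collect_weights(spec))
}

collect_weights <- function(spec) {
  if (inherits(spec, "submlp_ensemble"))
    return(lapply(spec$branches, collect_weights))
  if (inherits(spec, "fusion_spec"))
    return(list(a = collect_weights(spec$net_a),
                b = collect_weights(spec$net_b)))
  lapply(spec$layers, function(l) list(w = l$weights, d = l$delays))
}

## ---------------------------------------------------------------------------
## Simulation
## ---------------------------------------------------------------------------

# Split a dense layer's weights by unique axonal delay; returns a list of
# (delay, weight-matrix) pairs so the per-tick input is a short sum of
# matrix products.
split_by_delay <- function(l) {
  W <- l$weights
  if (is.null(l$delays)) return(list(list(d = 0L, W = W)))
  uds <- sort(unique(as.integer(l$delays)))
  lapply(uds, function(d) list(d = d, W = W * (l$delays == d)))
}

conv_same <- function(z, K) {
  # z: (C, H, W) numeric array; K: (k, k, C, F). Zero padding, stride 1.
  k <- dim(K)[1]
  C <- dim(z)[1]; H <- dim(z)[2]; W <- dim(z)[3]
  Fk <- dim(K)[4]
  pad <- (k - 1L) %/% 2L
  out <- array(0, c(Fk, H, W))
  zm <- matrix(z, nrow = C)                      # C x (H*W), column-major h fastest
  for (dy in seq_len(k)) {
    for (dx in seq_len(k)) {
      # input rows h + dy - 1 - pad, cols w + dx - 1 - pad
      oy <- dy - 1L - pad
      ox <- dx - 1L - pad
      hs <- seq_len(H) + oy
      ws <- seq_len(W) + ox
      hv <- hs >= 1L & hs <= H
      wv <- ws >= 1L & ws <= W
      if (!any(hv) || !any(wv)) next
      Km <- matrix(K[dy, dx, , ], nrow = C, ncol = Fk)
      sub <- z[, hs[hv], ws[wv], drop = FALSE]
      contrib <- crossprod(Km, matrix(sub, nrow = C))  # F x (sum(hv)*sum(wv))
      block <- array(0, c(Fk, H, W))
      block[, which(hv), which(wv)] <- contrib
      out <- out + block
    }
  }
  out
}

#' Run a spiking network on a rasterized input
#'
#' Simulates the network tick by tick for `ticks(raster) + extra_ticks`
#' ticks. The classification decision is the argmax of cumulative output
#' spike counts at the final tick; ties are broken by the larger final
#' membrane potential, then by the lowest class index — fully deterministic
#' given spec and raster.
#'
#' @param spec a `network_spec`, `submlp_ensemble` or `fusion_spec`.
#' @param raster a [spike_raster()] whose channel count matches the spec
#'   input (for ensembles: a list of four rasters; for fusion: a list
#'   `list(a = , b = )` of the two modality inputs).
#' @param extra_ticks additional silent ticks after stimulus end, letting
#'   spikes propagate to the readout (default 0).
#' @param return_layers if TRUE, also return each layer's per-tick spike
#'   history.
#' @return list with `counts` (per-class output spike counts), `trace`
#'   (classes x ticks output spike history), `decision` (1-based class
#'   index), `final_v` (output membrane at the final tick), `spike_totals`
#'   (named per-population total spike counts, input included) and
#'   optionally `layers`.
#' @export
run_network <- function(spec, raster, extra_ticks = 0L,
                        return_layers = FALSE) {
  UseMethod("run_network")
}

#' @export
run_network.network_spec <- function(spec, raster, extra_ticks = 0L,
                                     return_layers = FALSE) {
  if (!is_trained(spec)) stop("network is untrained (NULL weights)")
  counts_in <- raster$counts
  if (nrow(counts_in) != prod(spec$input_shape))
    stop("shape mismatch at input: raster has ", nrow(counts_in),
         " channels, spec expects ", prod(spec$input_shape))
  T_in <- ncol(counts_in)
  T_tot <- T_in + as.integer(extra_ticks)
  L <- length(spec$layers)

  hist <- vector("list", L + 1L)
  hist[[1]] <- cbind(counts_in,
                     matrix(0, nrow(counts_in), T_tot - T_in))
  states <- vector("list", L)
  wsplit <- vector("list", L)
  for (li in seq_len(L)) {
    l <- spec$layers[[li]]
    n_units <- prod(spec$output_shapes[[li]])
    hist[[li + 1L]] <- matrix(0, n_units, T_tot)
    if (l$kind %in% c("dense", "conv")) states[[li]] <- cuba_init(n_units)
    if (l$kind == "dense") wsplit[[li]] <- split_by_delay(l)
  }

  in_shapes <- c(list(spec$input_shape), spec$output_shapes)
  for (t in seq_len(T_tot)) {
    for (li in seq_len(L)) {
      l <- spec$layers[[li]]
      prev <- hist[[li]]
      out <- switch(
        l$kind,
        dense = {
          a <- numeric(l$units)
          for (pw in wsplit[[li]]) {
            tc <- t - 1L - pw$d
            if (tc >= 1L) a <- a + as.numeric(crossprod(pw$W, prev[, tc]))
          }
          st <- cuba_step(states[[li]], a, l$neuron)
          states[[li]] <- st$state
          as.numeric(st$spikes)
        },
        conv = {
          tc <- t - 1L
          a <- if (tc >= 1L) {
            z <- array(prev[, tc], dim = in_shapes[[li]])
            as.numeric(conv_same(z, l$weights))
          } else numeric(prod(spec$output_shapes[[li]]))
          st <- cuba_step(states[[li]], a, l$neuron)
          states[[li]] <- st$state
          as.numeric(st$spikes)
        },
        pool = {
          z <- array(prev[, t] > 0, dim = in_shapes[[li]])
          C <- dim(z)[1]; H <- dim(z)[2]; W <- dim(z)[3]
          o <- z[, seq(1, H, 2), seq(1, W, 2), drop = FALSE] |
            z[, seq(2, H, 2), seq(1, W, 2), drop = FALSE] |
            z[, seq(1, H, 2), seq(2, W, 2), drop = FALSE] |
            z[, seq(2, H, 2), seq(2, W, 2), drop = FALSE]
          as.numeric(o)
        },
        flatten = prev[, t])
      hist[[li + 1L]][, t] <- out
    }
  }

  trace <- hist[[L + 1L]]
  counts <- rowSums(trace)
  final_v <- states[[L]]$v
  totals <- vapply(hist, sum, 0)
  names(totals) <- c("input", paste0("layer", seq_len(L)))
  res <- list(counts = counts, trace = trace,
              decision = decide(counts, final_v), final_v = final_v,
              spike_totals = totals)
  if (return_layers) res$layers <- hist[-1L]
  res
}

# argmax of counts; ties broken by larger final membrane, then lowest index
decide <- function(counts, final_v = rep(0, length(counts))) {
  best <- which(counts == max(counts))
  if (length(best) > 1L) best <- best[final_v[best] == max(final_v[best])]
  best[1L]
}

## ---------------------------------------------------------------------------
## subMLP ensembles and fusion
## ---------------------------------------------------------------------------

#' Four-branch subMLP ensemble (one branch per crossbar core)
#'
#' The four branches share a topology but not weights; each processes one
#' of the four parity-subsampled event streams. `sum_outputs` sums the four
#' branches' output spike counts into the class scores; `concat_hidden`
#' exports the concatenated hidden-layer spike trains (e.g. 4 x 210 = 840
#' wide) for sensor fusion.
#'
#' @param branches list of four `network_spec`s with identical topology.
#' @param mode "sum_outputs" or "concat_hidden".
#' @export
submlp_ensemble <- function(branches, mode = c("sum_outputs",
                                               "concat_hidden")) {
  mode <- match.arg(mode)
  if (length(branches) != 4L) stop("exactly 4 branch networks required")
  structure(list(branches = branches, mode = mode,
                 name = "submlp_ensemble",
                 chip_model = branches[[1]]$chip_model),
            class = "submlp_ensemble")
}

#' @export
run_network.submlp_ensemble <- function(spec, raster, extra_ticks = 0L,
                                        return_layers = FALSE) {
  if (length(raster) != 4L) stop("ensemble expects exactly 4 input rasters")
  runs <- lapply(seq_len(4L), function(k)
    run_network(spec$branches[[k]], raster[[k]], extra_ticks = extra_ticks,
                return_layers = TRUE))
  if (spec$mode == "sum_outputs") {
    counts <- Reduce(`+`, lapply(runs, `[[`, "counts"))
    final_v <- Reduce(`+`, lapply(runs, `[[`, "final_v"))
    trace <- Reduce(`+`, lapply(runs, `[[`, "trace"))
    res <- list(counts = counts, trace = trace,
                decision = decide(counts, final_v), final_v = final_v,
                spike_totals = Reduce(`+`, lapply(runs, `[[`, "spike_totals")),
                branch_runs = if (return_layers) runs)
  } else {
    Lb <- length(spec$branches[[1]]$layers)
    hidden <- do.call(rbind, lapply(runs, function(r) r$layers[[Lb - 1L]]))
    res <- list(hidden_trace = hidden, hidden_counts = rowSums(hidden),
                spike_totals = Reduce(`+`, lapply(runs, `[[`, "spike_totals")),
                branch_runs = if (return_layers) runs)
  }
  res
}

penultimate_width <- function(spec) {
  if (inherits(spec, "submlp_ensemble")) {
    b <- spec$branches[[1]]
    return(4L * b$layers[[length(b$layers) - 1L]]$units)
  }
  L <- length(spec$layers)
  prod(spec$output_shapes[[L - 1L]])
}

#' Build a late sensor-fusion network from two trained networks
#'
#' Concatenates the penultimate (hidden) spike outputs of both networks and
#' feeds them to a fresh 5-unit output layer; all upstream weights are
#' frozen. E.g. a 230-hidden EMG net plus a four-branch 210-hidden ensemble
#' gives a 1,070-wide fusion input; a 128-hidden MLP plus a 512-hidden CNN
#' gives 640.
#'
#' @param net_a,net_b trained `network_spec`s (or a `submlp_ensemble` whose
#'   branch hidden layers are concatenated).
#' @param output_quant [quant_spec()] for the new output layer.
#' @param n_classes output units (default 5).
#' @param neuron [neuron_config()] for the output layer.
#' @return a `fusion_spec` with an untrained head; see
#'   [retrain_fusion_head()].
#' @export
build_fusion <- function(net_a, net_b, output_quant = quant_spec(),
                         n_classes = 5L,
                         neuron = neuron_config(current_decay = 4096,
                                                voltage_decay = 0)) {
  if (!is_trained(net_a) || !is_trained(net_b))
    stop("both networks must be trained before fusion")
  wa <- penultimate_width(net_a)
  wb <- penultimate_width(net_b)
  head <- layer_dense(n_classes, weights = NULL, neuron = neuron,
                      quant = output_quant)
  structure(list(net_a = net_a, net_b = net_b, head = head,
                 input_width = wa + wb, widths = c(a = wa, b = wb),
                 name = paste0("fusion(", net_a$name %||% "a", "+",
                               net_b$name %||% "b", ")")),
            class = "fusion_spec")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Per-tick hidden (penultimate) spike trace of a trained net on a raster.
hidden_trace <- function(spec, raster, extra_ticks = 0L) {
  if (inherits(spec, "submlp_ensemble")) {
    sp <- spec
    sp$mode <- "concat_hidden"
    r <- run_network(sp, raster, extra_ticks = extra_ticks)
    return(list(trace = r$hidden_trace, spike_totals = r$spike_totals))
  }
  r <- run_network(spec, raster, extra_ticks = extra_ticks,
                   return_layers = TRUE)
  L <- length(spec$layers)
  list(trace = r$layers[[L - 1L]], spike_totals = r$spike_totals)
}

#' @export
run_network.fusion_spec <- function(spec, raster, extra_ticks = 0L,
                                    return_layers = FALSE) {
  if (is.null(spec$head$weights)) stop("fusion head is untrained")
  if (!is.list(raster) || is.null(raster$a) || is.null(raster$b))
    stop("fusion input must be list(a = <raster>, b = <raster>)")
  ha <- hidden_trace(spec$net_a, raster$a, extra_ticks)
  hb <- hidden_trace(spec$net_b, raster$b, extra_ticks)
  hin <- rbind(ha$trace, hb$trace)
  T_tot <- ncol(hin)
  st <- cuba_init(spec$head$units)
  trace <- matrix(0, spec$head$units, T_tot)
  for (t in seq_len(T_tot)) {
    a <- if (t >= 2L) as.numeric(crossprod(spec$head$weights, hin[, t - 1L]))
         else numeric(spec$head$units)
    s <- cuba_step(st, a, spec$head$neuron)
    st <- s$state
    trace[, t] <- as.numeric(s$spikes)
  }
  counts <- rowSums(trace)
  totals <- c(ha$spike_totals["input"] + hb$spike_totals["input"],
              hidden = sum(hin), head = sum(trace))
  names(totals)[1] <- "input"
  list(counts = counts, trace = trace,
       decision = decide(counts, st$v), final_v = st$v,
       spike_totals = totals,
       hidden_counts = rowSums(hin))
}

## ---------------------------------------------------------------------------
## Reference topologies
## ---------------------------------------------------------------------------

#' Reference network topologies of the modelled chips
#'
#' Untrained specs for: the 3-bit 16-230-5 EMG MLP (ODIN), one binary
#' 400-210-5 DVS subMLP branch and its four-branch ensemble (MorphIC), the
#' 8-bit 16-128d-128d-5 EMG MLP with trainable axonal delays and the
#' 40x40x2-8c3-2p-16c3-2p-32c3-512-5 DVS CNN (Loihi, CUBA decay constants
#' 1024 and, for the CNN voltage, 128).
#'
#' @param threshold firing threshold used for every layer (trained or
#'   searched later).
#' @name reference_topologies
NULL

# ODIN/MorphIC neurons: voltage-only LIF (full current decay), perfect
# integrator by default — thresholds come from the ANN-to-SNN mapping.
lif_mapped <- function(threshold = 1) {
  neuron_config(current_decay = 4096, voltage_decay = 0,
                threshold = threshold)
}

#' @rdname reference_topologies
#' @export
spec_odin_emg <- function(threshold = 1) {
  network_spec("emg-odin",
               list(layer_dense(230L, neuron = lif_mapped(threshold),
                                quant = quant_spec("int3")),
                    layer_dense(5L, neuron = lif_mapped(threshold),
                                quant = quant_spec("int3"))),
               input_shape = 16L, chip_model = "odin")
}

#' @rdname reference_topologies
#' @export
spec_morphic_branch <- function(threshold = 1) {
  network_spec("dvs-morphic-branch",
               list(layer_dense(210L, neuron = lif_mapped(threshold),
                                quant = quant_spec("binary")),
                    layer_dense(5L, neuron = lif_mapped(threshold),
                                quant = quant_spec("binary"))),
               input_shape = 400L, chip_model = "morphic")
}

#' @rdname reference_topologies
#' @export
spec_morphic_dvs <- function(threshold = 1) {
  submlp_ensemble(lapply(1:4, function(k) spec_morphic_branch(threshold)),
                  mode = "sum_outputs")
}

#' @rdname reference_topologies
#' @export
spec_loihi_emg_mlp <- function(threshold = 1) {
  n <- neuron_config(current_decay = 1024, voltage_decay = 1024,
                     threshold = threshold)
  network_spec("emg-loihi",
               list(layer_dense(128L, neuron = n, quant = quant_spec("int8")),
                    layer_dense(128L, neuron = n, quant = quant_spec("int8")),
                    layer_dense(5L, neuron = n, quant = quant_spec("int8"))),
               input_shape = 16L, chip_model = "loihi")
}

#' @rdname reference_topologies
#' @export
spec_loihi_dvs_cnn <- function(threshold = 1) {
  n <- neuron_config(current_decay = 1024, voltage_decay = 128,
                     threshold = threshold)
  network_spec("dvs-loihi-cnn",
               list(layer_conv(8L, 3L, neuron = n, quant = quant_spec("int8")),
                    layer_pool(),
                    layer_conv(16L, 3L, neuron = n, quant = quant_spec("int8")),
                    layer_pool(),
                    layer_conv(32L, 3L, neuron = n, quant = quant_spec("int8")),
                    layer_flatten(),
                    layer_dense(512L, neuron = n, quant = quant_spec("int8")),
                    layer_dense(5L, neuron = n, quant = quant_spec("int8"))),
               input_shape = c(2L, 40L, 40L), chip_model = "loihi")
}

## ---------------------------------------------------------------------------
## Serialization (JSON)
## ---------------------------------------------------------------------------

#' Serialize a network spec to JSON
#'
#' Layers, quantization specs, neuron configs, weights and delays are all
#' stored inline (arrays with explicit dims), so the round-trip reproduces
#' the spec exactly up to numeric printing precision.
#'
#' @param spec a `network_spec`; @param path output file.
#' @export
spec_to_json <- function(spec, path) {
  enc_arr <- function(a) if (is.null(a)) NULL else
    list(dim = dim(a) %||% length(a), data = as.numeric(a))
  obj <- list(
    name = spec$name, chip_model = spec$chip_model,
    input_shape = spec$input_shape,
    layers = lapply(spec$layers, function(l) {
      o <- list(kind = l$kind)
      if (l$kind == "dense") {
        o$units <- l$units
        o$weights <- enc_arr(l$weights)
        o$delays <- enc_arr(l$delays)
      }
      if (l$kind == "conv") {
        o$filters <- l$filters
        o$kernel <- l$kernel
        o$weights <- enc_arr(l$weights)
      }
      if (l$kind %in% c("dense", "conv")) {
        o$neuron <- unclass(l$neuron)
        o$quant <- unclass(l$quant)
      }
      o
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a network spec back from JSON
#' @param path file written by [spec_to_json()].
#' @export
spec_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  dec_arr <- function(a) {
    if (is.null(a)) return(NULL)
    d <- unlist(a$dim)
    v <- unlist(a$data)
    if (length(d) > 1L) array(v, dim = d) else v
  }
  layers <- lapply(obj$layers, function(l) {
    if (l$kind == "pool") return(layer_pool())
    if (l$kind == "flatten") return(layer_flatten())
    neuron <- do.call(neuron_config, l$neuron)
    quant <- quant_spec(l$quant$kind, l$quant$scale)
    if (l$kind == "dense")
      layer_dense(l$units, weights = dec_arr(l$weights),
                  delays = dec_arr(l$delays), neuron = neuron, quant = quant)
    else
      layer_conv(l$filters, l$kernel, weights = dec_arr(l$weights),
                 neuron = neuron, quant = quant)
  })
  network_spec(obj$name, layers, unlist(obj$input_shape), obj$chip_model)
}
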