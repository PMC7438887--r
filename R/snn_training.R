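## Training: surrogate-gradient backprop-through-time for Loihi-style CUBA
## networks (quantized forward, full-precision shadow backward), and
## quantization-aware ANN training + ANN-to-SNN mapping with threshold
## search for the crossbar (ODIN/MorphIC) path.

#' Training configuration
#'
#' @param epochs training epochs (default 30).
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param seed RNG seed, recorded in the returned spec.
#' @param surrogate_width width parameter of the exponential spike-escape
#'   surrogate derivative `exp(-|v - threshold| / width) / (2 width)`.
#' @param train_delays train axonal delays (layers holding a delay matrix).
#' @param lr_delay learning rate for delay shadows.
#' @param step_hook optional `function(spec, step)` called with the
#'   quantization-closed spec after every optimizer step.
#' @export
train_config <- function(epochs = 30L, lr = 0.01, batch_size = 32L,
                         seed = 1L, surrogate_width = 0.5,
                         train_delays = FALSE, lr_delay = 0.05,
                         step_hook = NULL) {
  if (epochs <= 0) stop("epochs must be > 0")
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 surrogate_width = surrogate_width,
                 train_delays = train_delays, lr_delay = lr_delay,
                 step_hook = step_hook),
            class = "train_config")
}

## --- Adam ------------------------------------------------------------------

adam_init <- function(w) list(m = array(0, dim(w) %||% length(w)),
                              v = array(0, dim(w) %||% length(w)), t = 0L)

adam_step <- function(st, g, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mh <- st$m / (1 - b1^st$t)
  vh <- st$v / (1 - b2^st$t)
  st$delta <- lr * mh / (sqrt(vh) + eps)
  st
}

## --- Weight init -----------------------------------------------------------

layer_scale <- function(shadow, kind) {
  mx <- max(abs(shadow))
  if (mx == 0) mx <- 1
  switch(kind, binary = 1,
         int3 = mx / 4, int8 = mx / 127, float = 1)
}

requantize <- function(shadow, q) {
  q$scale <- layer_scale(shadow, q$kind)
  list(w = quantize(shadow, q), q = q)
}

#' Initialize the weights (and optionally delays) of an untrained spec
#'
#' Weights are drawn N(0, 1/sqrt(fan_in)) and immediately projected onto
#' the layer's quantization spec (per-layer scale from the shadow maximum);
#' delay matrices for the requested dense layers are drawn uniformly from
#' `{0..max_delay}` ticks.
#'
#' @param spec a `network_spec` or `submlp_ensemble`.
#' @param seed RNG seed.
#' @param delay_layers indices of dense layers to equip with per-synapse
#'   axonal delays.
#' @param max_delay largest initial delay in ticks.
#' @export
init_network <- function(spec, seed = 1L, delay_layers = integer(0),
                         max_delay = 5L) {
  if (inherits(spec, "submlp_ensemble")) {
    spec$branches <- lapply(seq_along(spec$branches), function(k)
      init_network(spec$branches[[k]], seed = seed + k,
                   delay_layers = delay_layers, max_delay = max_delay))
    return(spec)
  }
  set.seed(seed)
  shapes <- c(list(spec$input_shape), spec$output_shapes)
  for (li in seq_along(spec$layers)) {
    l <- spec$layers[[li]]
    if (l$kind == "dense" && is.null(l$weights)) {
      n_in <- prod(shapes[[li]])
      sh <- matrix(rnorm(n_in * l$units, sd = 1 / sqrt(n_in)), n_in, l$units)
      rq <- requantize(sh, l$quant)
      l$weights <- rq$w
      l$quant <- rq$q
      attr(l$weights, "shadow") <- sh
      if (li %in% delay_layers)
        l$delays <- matrix(sample(0:max_delay, n_in * l$units, TRUE),
                           n_in, l$units)
    } else if (l$kind == "conv" && is.null(l$weights)) {
      n_in <- prod(shapes[[li]])
      fan <- l$kernel^2 * shapes[[li]][1]
      sh <- array(rnorm(l$kernel^2 * shapes[[li]][1] * l$filters,
                        sd = 1 / sqrt(fan)),
                  c(l$kernel, l$kernel, shapes[[li]][1], l$filters))
      rq <- requantize(sh, l$quant)
      l$weights <- rq$w
      l$quant <- rq$q
      attr(l$weights, "shadow") <- sh
    }
    spec$layers[[li]] <- l
  }
  network_spec(spec$name, spec$layers, spec$input_shape, spec$chip_model)
}

## --- Surrogate-gradient BPTT ----------------------------------------------

# escape-rate surrogate and its smooth primitive
esc_deriv <- function(u, theta, width) exp(-abs(u - theta) / width) / (2 * width)
esc_smooth <- function(u, theta, width) {
  ifelse(u < theta, 0.5 * exp((u - theta) / width),
         1 - 0.5 * exp(-(u - theta) / width))
}

rasters_to_array <- function(rasters) {
  T_ <- ncol(rasters[[1]]$counts)
  C <- nrow(rasters[[1]]$counts)
  X <- array(0, c(length(rasters), C, T_))
  for (n in seq_along(rasters)) X[n, , ] <- rasters[[n]]$counts
  X
}

#' Loss and gradients of a dense spiking network (BPTT)
#'
#' Forward-simulates the network on a batch of rasters and backpropagates
#' through time. In spiking mode the forward pass uses the hard threshold
#' and the backward pass the exponential escape-rate surrogate; with
#' `smooth = TRUE` both passes use the smooth escape-rate relaxation, so the
#' returned gradient is the exact gradient of the returned (smoothed) loss
#' — this is what the finite-difference check validates. The loss is
#' softmax cross-entropy on output spike counts.
#'
#' @param spec all-dense `network_spec` with trained/initialized weights.
#' @param X array `(N, channels, ticks)` of input spike counts.
#' @param y integer class labels (1-based), length N.
#' @param width surrogate width.
#' @param smooth use the fully smooth relaxation (for gradient checking).
#' @return list `(loss, accuracy, grads, delay_grads, counts)`.
#' @export
snn_gradient <- function(spec, X, y, width = 0.5, smooth = FALSE) {
  N <- dim(X)[1]
  T_ <- dim(X)[3]
  L <- length(spec$layers)
  K <- spec$layers[[L]]$units

  S <- vector("list", L + 1L)          # per layer: list over t of N x units
  U <- vector("list", L)
  S[[1]] <- lapply(seq_len(T_), function(t) matrix(X[, , t], N, dim(X)[2]))

  for (li in seq_len(L)) {
    l <- spec$layers[[li]]
    if (l$kind != "dense") stop("snn_gradient supports dense layers only")
    ai <- (DECAY_SCALE - l$neuron$current_decay) / DECAY_SCALE
    av <- (DECAY_SCALE - l$neuron$voltage_decay) / DECAY_SCALE
    th <- l$neuron$threshold
    ws <- split_by_delay(l)
    I <- V <- matrix(0, N, l$units)
    U[[li]] <- S[[li + 1L]] <- vector("list", T_)
    for (t in seq_len(T_)) {
      A <- matrix(0, N, l$units)
      for (pw in ws) {
        tc <- t - 1L - pw$d
        if (tc >= 1L) A <- A + S[[li]][[tc]] %*% pw$W
      }
      I <- ai * I + A
      Ut <- av * V + I
      St <- if (smooth) esc_smooth(Ut, th, width)
            else (Ut >= th) * 1
      V <- Ut * (1 - St)
      U[[li]][[t]] <- Ut
      S[[li + 1L]][[t]] <- St
    }
  }

  counts <- Reduce(`+`, S[[L + 1L]])
  z <- counts - apply(counts, 1L, max)
  P <- exp(z) / rowSums(exp(z))
  Y <- matrix(0, N, K)
  Y[cbind(seq_len(N), y)] <- 1
  loss <- -mean(log(pmax(P[cbind(seq_len(N), y)], 1e-12)))
  acc <- mean(max.col(counts, ties.method = "first") == y)

  dS_out <- (P - Y) / N                 # same for every tick
  dS <- lapply(seq_len(T_), function(t) dS_out)
  grads <- vector("list", L)
  dgrads <- vector("list", L)
  for (li in rev(seq_len(L))) {
    l <- spec$layers[[li]]
    ai <- (DECAY_SCALE - l$neuron$current_decay) / DECAY_SCALE
    av <- (DECAY_SCALE - l$neuron$voltage_decay) / DECAY_SCALE
    th <- l$neuron$threshold
    ws <- split_by_delay(l)
    n_in <- nrow(l$weights)
    dW <- matrix(0, n_in, l$units)
    dD <- if (!is.null(l$delays)) matrix(0, n_in, l$units)
    dS_prev <- lapply(seq_len(T_), function(t)
      matrix(0, N, n_in))
    dI_next <- matrix(0, N, l$units)
    dV_next <- matrix(0, N, l$units)     # gradient into V[t] from tick t+1
    for (t in rev(seq_len(T_))) {
      Ut <- U[[li]][[t]]
      St <- S[[li + 1L]][[t]]
      fp <- esc_deriv(Ut, th, width)
      dU <- dS[[t]] * fp + dV_next * ((1 - St) - Ut * fp)
      dI <- dU + ai * dI_next
      dV_next <- av * dU
      dI_next <- dI
      # dA = dI; accumulate weight / delay / input gradients
      for (pw in ws) {
        tc <- t - 1L - pw$d
        if (tc >= 1L) {
          mask <- if (is.null(l$delays)) 1 else (l$delays == pw$d)
          dW <- dW + crossprod(S[[li]][[tc]], dI) * mask
          dS_prev[[tc]] <- dS_prev[[tc]] + dI %*% t(pw$W)
          if (!is.null(dD)) {
            prev_diff <- S[[li]][[tc]] -
              (if (tc >= 2L) S[[li]][[tc - 1L]] else 0)
            dD <- dD - (l$weights * mask) * crossprod(prev_diff, dI)
          }
        }
      }
    }
    grads[[li]] <- dW
    dgrads[[li]] <- dD
    dS <- dS_prev
  }
  list(loss = loss, accuracy = acc, grads = grads, delay_grads = dgrads,
       counts = counts)
}

#' Surrogate-gradient training of a Loihi-style spiking network
#'
#' SLAYER-style training directly in the spiking domain: the forward pass
#' runs the hard-threshold CUBA dynamics with quantized (int8) weights and
#' integer delays, the backward pass uses full-precision shadow variables
#' and the exponential spike-escape surrogate derivative. Weights are
#' re-projected onto the representable set after every Adam step
#' (quantization closure); continuous delay shadows are rounded to integer
#' ticks in `[0, 63]` at the end of each epoch.
#'
#' @param spec all-dense `network_spec` with `chip_model = "loihi"`
#'   (untrained specs are initialized with the config seed).
#' @param data list with `rasters` (list of [spike_raster()]) and `labels`
#'   (1-based integer classes).
#' @param cfg a [train_config()].
#' @return the trained, quantization-closed `network_spec` (attributes:
#'   `history` = per-epoch loss/accuracy, `seed`).
#' @export
train_surrogate <- function(spec, data, cfg = train_config()) {
  if (spec$chip_model != "loihi")
    stop("train_surrogate expects a loihi-model spec")
  if (!is_trained(spec))
    spec <- init_network(spec, seed = cfg$seed,
                         delay_layers = if (cfg$train_delays)
                           which(vapply(spec$layers, function(l)
                             l$kind == "dense", TRUE)) else integer(0))
  X <- rasters_to_array(data$rasters)
  y <- data$labels
  N <- dim(X)[1]
  L <- length(spec$layers)
  shadows <- lapply(spec$layers, function(l) attr(l$weights, "shadow") %||%
                      l$weights)
  dshadows <- lapply(spec$layers, function(l)
    if (is.null(l$delays)) NULL else l$delays * 1.0)
  opt <- lapply(shadows, adam_init)
  opt_d <- lapply(dshadows, function(d) if (!is.null(d)) adam_init(d))
  set.seed(cfg$seed)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     accuracy = numeric(0))
  step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(N)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (b in batches) {
      g <- snn_gradient(spec, X[b, , , drop = FALSE], y[b],
                        width = cfg$surrogate_width)
      if (!is.finite(g$loss))
        stop("non-finite loss at epoch ", ep,
             " (batch of ", length(b), "); weight scales: ",
             paste(signif(vapply(spec$layers, function(l) l$quant$scale, 0), 3),
                   collapse = ", "))
      ep_loss <- ep_loss + g$loss * length(b)
      for (li in seq_len(L)) {
        opt[[li]] <- adam_step(opt[[li]], g$grads[[li]], cfg$lr)
        shadows[[li]] <- shadows[[li]] - opt[[li]]$delta
        rq <- requantize(shadows[[li]], spec$layers[[li]]$quant)
        spec$layers[[li]]$weights <- rq$w
        spec$layers[[li]]$quant <- rq$q
        if (cfg$train_delays && !is.null(dshadows[[li]])) {
          opt_d[[li]] <- adam_step(opt_d[[li]], g$delay_grads[[li]],
                                   cfg$lr_delay)
          dshadows[[li]] <- pmin(pmax(dshadows[[li]] - opt_d[[li]]$delta, 0),
                                 63)
        }
      }
      step <- step + 1L
      if (!is.null(cfg$step_hook)) cfg$step_hook(spec, step)
    }
    # delays live on the integer grid between epochs
    for (li in seq_len(L)) if (!is.null(dshadows[[li]]))
      spec$layers[[li]]$delays <- round(dshadows[[li]])
    ev <- snn_gradient(spec, X, y, width = cfg$surrogate_width)
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / N,
                                   accuracy = ev$accuracy))
  }
  for (li in seq_len(L))
    attr(spec$layers[[li]]$weights, "shadow") <- shadows[[li]]
  attr(spec, "history") <- hist
  attr(spec, "seed") <- cfg$seed
  spec
}

## --- Quantization-aware ANN training (crossbar path) -----------------------

ann_forward <- function(spec, x) {
  # ReLU MLP with the spec's (quantized) weights; returns activations per
  # layer, final layer linear (softmax applied by callers).
  acts <- list()
  h <- x
  L <- length(spec$layers)
  for (li in seq_len(L)) {
    h <- h %*% spec$layers[[li]]$weights
    if (li < L) h <- pmax(h, 0)
    acts[[li]] <- h
  }
  acts
}

#' Quantization-aware training of a rate-based (ANN) network
#'
#' Straight-through-estimator training of a ReLU MLP whose forward weights
#' are projected onto the chip's representable set (int3 for ODIN, binary
#' for MorphIC) at every step, full-precision shadows receiving the Adam
#' updates. Inputs are per-chunk spike-count features; no biases are used
#' (crossbar neurons carry thresholds, not biases). For a
#' [submlp_ensemble()], the four branches are trained independently on
#' their four input streams.
#'
#' @param spec untrained `network_spec` (dense only) or `submlp_ensemble`.
#' @param data list: `x` = N x D spike-count matrix (for ensembles, a list
#'   of four such matrices), `y` = 1-based labels.
#' @param cfg a [train_config()].
#' @return trained spec with quantized weights (shadows kept as attribute).
#' @export
train_quantized_ann <- function(spec, data, cfg = train_config()) {
  UseMethod("train_quantized_ann")
}

#' @export
train_quantized_ann.submlp_ensemble <- function(spec, data,
                                                cfg = train_config()) {
  stopifnot(is.list(data$x), length(data$x) == 4L)
  spec$branches <- lapply(seq_len(4L), function(k) {
    cfg_k <- cfg
    cfg_k$seed <- cfg$seed + k
    train_quantized_ann(spec$branches[[k]],
                        list(x = data$x[[k]], y = data$y), cfg_k)
  })
  spec
}

#' @export
train_quantized_ann.network_spec <- function(spec, data,
                                             cfg = train_config()) {
  if (!is_trained(spec)) spec <- init_network(spec, seed = cfg$seed)
  x <- data$x
  y <- data$y
  N <- nrow(x)
  L <- length(spec$layers)
  K <- spec$layers[[L]]$units
  shadows <- lapply(spec$layers, function(l) attr(l$weights, "shadow") %||%
                      l$weights)
  opt <- lapply(shadows, adam_init)
  set.seed(cfg$seed)
  step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(N)
    for (b in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      xb <- x[b, , drop = FALSE]
      acts <- ann_forward(spec, xb)
      z <- acts[[L]]
      z <- z - apply(z, 1L, max)
      P <- exp(z) / rowSums(exp(z))
      Y <- matrix(0, length(b), K)
      Y[cbind(seq_along(b), y[b])] <- 1
      if (any(!is.finite(P))) stop("non-finite loss at epoch ", ep)
      d <- (P - Y) / length(b)
      for (li in rev(seq_len(L))) {
        a_prev <- if (li == 1L) xb else acts[[li - 1L]]
        gW <- crossprod(a_prev, d)
        if (li > 1L)
          d <- (d %*% t(spec$layers[[li]]$weights)) * (acts[[li - 1L]] > 0)
        opt[[li]] <- adam_step(opt[[li]], gW, cfg$lr)
        shadows[[li]] <- shadows[[li]] - opt[[li]]$delta
        rq <- requantize(shadows[[li]], spec$layers[[li]]$quant)
        spec$layers[[li]]$weights <- rq$w
        spec$layers[[li]]$quant <- rq$q
      }
      step <- step + 1L
      if (!is.null(cfg$step_hook)) cfg$step_hook(spec, step)
    }
  }
  for (li in seq_len(L))
    attr(spec$layers[[li]]$weights, "shadow") <- shadows[[li]]
  attr(spec, "seed") <- cfg$seed
  spec
}

#' ANN classification accuracy on count features
#' @param spec trained ANN `network_spec` or `submlp_ensemble`.
#' @param data list `(x, y)` as in [train_quantized_ann()].
#' @export
ann_accuracy <- function(spec, data) {
  scores <- ann_scores(spec, data$x)
  mean(max.col(scores, ties.method = "first") == data$y)
}

ann_scores <- function(spec, x) {
  if (inherits(spec, "submlp_ensemble")) {
    return(Reduce(`+`, lapply(seq_len(4L), function(k) {
      acts <- ann_forward(spec$branches[[k]], x[[k]])
      acts[[length(acts)]]
    })))
  }
  acts <- ann_forward(spec, x)
  acts[[length(acts)]]
}

## --- ANN-to-SNN mapping with threshold search ------------------------------

#' Per-layer firing-threshold search specification
#'
#' Candidate thresholds are `multiplier * base_l`, where `base_l` is the
#' 99th percentile of the layer's positive ANN pre-activations on the
#' calibration data divided by `spikes_target` — i.e. at multiplier 1 the
#' most active neurons emit about `spikes_target` spikes per chunk. The
#' candidate with the best validation accuracy wins; near-ties (within
#' `tie_tol`) are broken toward the candidate whose mean hidden firing rate
#' is closest to `target_rate` (used to balance EMG and DVS hidden
#' activities before fusion).
#'
#' @param multipliers non-empty numeric grid of threshold multipliers.
#' @param spikes_target nominal spikes per chunk for the most active units.
#' @param tie_tol accuracy window treated as a tie.
#' @export
threshold_search_spec <- function(multipliers = c(0.5, 1, 2, 4),
                                  spikes_target = 20, tie_tol = 0.01) {
  if (length(multipliers) == 0) stop("threshold grid must be non-empty")
  structure(list(multipliers = multipliers, spikes_target = spikes_target,
                 tie_tol = tie_tol),
            class = "threshold_search_spec")
}

set_thresholds <- function(spec, th) {
  if (inherits(spec, "submlp_ensemble")) {
    spec$branches <- lapply(spec$branches, set_thresholds, th = th)
    return(spec)
  }
  for (li in seq_along(spec$layers))
    spec$layers[[li]]$neuron <- lif_mapped(th[min(li, length(th))])
  spec
}

ann_bases <- function(ann, x_cal) {
  # 99th percentile of positive pre-activations per layer
  if (inherits(ann, "submlp_ensemble")) {
    per_branch <- lapply(seq_len(4L), function(k)
      ann_bases(ann$branches[[k]], x_cal[[k]]))
    return(Reduce(`+`, per_branch) / 4)
  }
  acts <- ann_forward(ann, x_cal)
  vapply(acts, function(a) {
    pos <- a[a > 0]
    if (length(pos) == 0) 1 else as.numeric(quantile(pos, 0.99))
  }, 0)
}

#' Map a trained quantization-aware ANN onto a spiking network
#'
#' Installs the ANN's (already chip-quantized) weights unchanged into a
#' voltage-only LIF network (full current decay, no voltage leak — a
#' perfect integrator, the standard rate-coding assumption) and selects
#' per-layer firing thresholds by grid search: for every candidate the SNN
#' is simulated on the validation samples and the candidate with the best
#' accuracy (rate-balance tie-break, see [threshold_search_spec()]) is
#' kept. For binary-weight (MorphIC) networks thresholds are rounded to
#' integers, matching per-neuron integer threshold registers.
#'
#' @param ann trained `network_spec`/`submlp_ensemble` from
#'   [train_quantized_ann()].
#' @param thresholds a [threshold_search_spec()].
#' @param cal list `(x, y)` of count features for calibration of the bases.
#' @param val list `(rasters, y)`: validation rasters (list; for ensembles
#'   a list of 4-raster lists) and labels for the grid search.
#' @param target_rate optional mean hidden firing rate (spikes per chunk
#'   per neuron) to balance toward on near-ties.
#' @return the spiking spec, with attributes `hidden_rate` (mean hidden
#'   spikes per chunk per neuron at the selected threshold), `threshold`
#'   and `search` (the per-candidate table).
#' @export
ann_to_snn <- function(ann, thresholds = threshold_search_spec(), cal, val,
                       target_rate = NULL) {
  if (!is_trained(ann)) stop("ann must be trained")
  bases <- ann_bases(ann, cal$x)
  bases <- bases / thresholds$spikes_target
  results <- data.frame(multiplier = thresholds$multipliers,
                        accuracy = NA_real_, hidden_rate = NA_real_,
                        output_spikes = NA_real_)
  cands <- vector("list", length(thresholds$multipliers))
  for (ci in seq_along(thresholds$multipliers)) {
    th <- bases * thresholds$multipliers[ci]
    if (inherits(ann, "submlp_ensemble") ||
        ann$layers[[1]]$quant$kind == "binary")
      th <- pmax(round(th), 1)
    cand <- set_thresholds(ann, th)
    ev <- snn_eval(cand, val$rasters, val$y)
    results$accuracy[ci] <- ev$accuracy
    results$hidden_rate[ci] <- ev$hidden_rate
    results$output_spikes[ci] <- ev$output_spikes
    cands[[ci]] <- list(spec = cand, th = th)
  }
  if (all(results$output_spikes == 0))
    stop("network silent at every threshold grid point; ",
         "extend the grid toward smaller multipliers")
  best_acc <- max(results$accuracy)
  ok <- which(results$accuracy >= best_acc - thresholds$tie_tol)
  pick <- if (!is.null(target_rate) && length(ok) > 1L)
    ok[which.min(abs(results$hidden_rate[ok] - target_rate))]
  else ok[which.max(results$accuracy[ok])]
  out <- cands[[pick]]$spec
  attr(out, "hidden_rate") <- results$hidden_rate[pick]
  attr(out, "threshold") <- cands[[pick]]$th
  attr(out, "search") <- results
  out
}

# Spiking evaluation of a net / ensemble on a list of rasters; reports
# accuracy, mean hidden rate (spikes per chunk per hidden neuron) and total
# output spikes. Uses the batched engine on the dense no-delay fast path.
snn_eval <- function(spec, rasters, y, extra_ticks = 2L) {
  n <- length(rasters)
  hidden_n <- penultimate_width(spec)
  if (is_dense_nodelay(spec)) {
    if (inherits(spec, "submlp_ensemble")) {
      Xs <- lapply(seq_len(4L), function(k)
        stack_rasters(lapply(rasters, `[[`, k)))
      fb <- snn_forward_batch(spec, Xs, extra_ticks)
      hid <- sum(vapply(fb$spike_totals, function(s)
        sum(s[-c(1L, length(s))]), 0))
    } else {
      fb <- snn_forward_batch(spec, stack_rasters(rasters), extra_ticks)
      hid <- sum(fb$spike_totals[-c(1L, length(fb$spike_totals))])
    }
    return(list(accuracy = mean(fb$decisions == y),
                hidden_rate = hid / (n * hidden_n),
                output_spikes = sum(fb$counts),
                predictions = fb$decisions))
  }
  pred <- integer(n)
  hid <- 0
  outs <- 0
  for (i in seq_len(n)) {
    r <- run_network(spec, rasters[[i]], extra_ticks = extra_ticks)
    pred[i] <- r$decision
    tot <- r$spike_totals
    hid <- hid + sum(tot[grepl("layer", names(tot))]) - tot[length(tot)]
    outs <- outs + sum(r$counts)
  }
  list(accuracy = mean(pred == y), hidden_rate = hid / (n * hidden_n),
       output_spikes = outs, predictions = pred)
}

## --- Fusion head retraining -------------------------------------------------

#' Retrain only the output layer of a fusion network
#'
#' The upstream (single-modality) networks are frozen — their weight hash
#' is guaranteed unchanged — and only the fresh 5-unit head is trained, by
#' quantization-aware STE on the concatenated penultimate spike counts.
#' The head firing threshold is then selected from the grid by maximizing
#' count-domain validation accuracy.
#'
#' @param fused a `fusion_spec` from [build_fusion()].
#' @param data list: either `hidden` (N x input_width matrix of
#'   concatenated penultimate spike counts) or `a`/`b` (per-modality raster
#'   lists, from which hidden counts are computed), plus `y` labels.
#' @param cfg a [train_config()].
#' @param thresholds a [threshold_search_spec()] for the head threshold.
#' @return the `fusion_spec` with a trained head (upstream untouched).
#' @export
retrain_fusion_head <- function(fused, data, cfg = train_config(),
                                thresholds = threshold_search_spec()) {
  hash_before <- weight_hash(list_upstream(fused))
  H <- data$hidden %||% fusion_hidden_counts(fused, data$a, data$b)
  head_spec <- network_spec(
    "fusion-head",
    list(layer_dense(fused$head$units, neuron = fused$head$neuron,
                     quant = fused$head$quant)),
    input_shape = ncol(H), chip_model = "none")
  head_spec <- train_quantized_ann(head_spec, list(x = H, y = data$y), cfg)
  W <- head_spec$layers[[1]]$weights
  attr(W, "shadow") <- NULL
  # head threshold: count-domain perfect-integrator approximation
  pre <- H %*% W
  base <- {
    pos <- pre[pre > 0]
    (if (length(pos)) as.numeric(quantile(pos, 0.99)) else 1) /
      thresholds$spikes_target
  }
  best <- NULL
  for (m in thresholds$multipliers) {
    th <- base * m
    sc <- floor(pmax(pre, 0) / th)
    acc <- mean(max.col(sc, ties.method = "first") == data$y)
    if (is.null(best) || acc > best$acc) best <- list(acc = acc, th = th)
  }
  fused$head$weights <- W
  fused$head$quant <- head_spec$layers[[1]]$quant   # carries the scale
  fused$head$neuron$threshold <- best$th
  stopifnot(identical(hash_before, weight_hash(list_upstream(fused))))
  attr(fused, "head_val_accuracy") <- best$acc
  fused
}

list_upstream <- function(fused) {
  structure(list(net_a = fused$net_a, net_b = fused$net_b,
                 head = list(kind = "dense", weights = NULL,
                             quant = fused$head$quant)),
            class = "fusion_spec")
}

#' Concatenated penultimate spike counts of a fusion network
#' @param fused a `fusion_spec`.
#' @param rasters_a,rasters_b per-modality input raster lists (same length).
#' @export
fusion_hidden_counts <- function(fused, rasters_a, rasters_b) {
  n <- length(rasters_a)
  H <- matrix(0, n, fused$input_width)
  for (i in seq_len(n)) {
    ha <- hidden_trace(fused$net_a, rasters_a[[i]])
    hb <- hidden_trace(fused$net_b, rasters_b[[i]])
    H[i, ] <- c(rowSums(ha$trace), rowSums(hb$trace))
  }
  H
}
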