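## Batched (vectorized over samples) forward simulation for all-dense,
## no-delay networks — the fast path used by the evaluation pipeline for
## the crossbar (ODIN/MorphIC) networks. Semantics are identical to
## run_network(): one tick transport latency per dense stage, CUBA-LIF
## update, reset to zero. Equivalence is covered by tests.

is_dense_nodelay <- function(spec) {
  if (inherits(spec, "submlp_ensemble"))
    return(all(vapply(spec$branches, is_dense_nodelay, TRUE)))
  all(vapply(spec$layers, function(l)
    l$kind == "dense" && is.null(l$delays), TRUE))
}

#' Stack a list of spike rasters into an (N, channels, ticks) array
#' @param rasters list of [spike_raster()] with identical dimensions.
#' @export
stack_rasters <- function(rasters) {
  T_ <- ncol(rasters[[1]]$counts)
  C <- nrow(rasters[[1]]$counts)
  X <- array(0, c(length(rasters), C, T_))
  for (n in seq_along(rasters)) X[n, , ] <- rasters[[n]]$counts
  X
}

# stateful stepper over a stack of dense CUBA layers for a batch of N
# samples; step(input_t) returns this tick's emissions per layer, using
# every population's previous-tick emissions (one-tick transport latency)
make_stack <- function(layers, N) {
  L <- length(layers)
  I <- V <- lapply(layers, function(l) matrix(0, N, l$units))
  B <- c(list(NULL), lapply(layers, function(l) matrix(0, N, l$units)))
  ai <- vapply(layers, function(l)
    (DECAY_SCALE - l$neuron$current_decay) / DECAY_SCALE, 0)
  av <- vapply(layers, function(l)
    (DECAY_SCALE - l$neuron$voltage_decay) / DECAY_SCALE, 0)
  th <- vapply(layers, function(l) l$neuron$threshold, 0)
  first <- TRUE

  step <- function(input_t) {
    out <- vector("list", L)
    for (li in seq_len(L)) {
      A <- if (is.null(B[[li]])) matrix(0, N, layers[[li]]$units)
           else B[[li]] %*% layers[[li]]$weights
      I[[li]] <<- ai[li] * I[[li]] + A
      U <- av[li] * V[[li]] + I[[li]]
      S <- (U >= th[li]) * 1
      V[[li]] <<- U * (1 - S)
      out[[li]] <- S
    }
    B[[1]] <<- input_t
    for (li in seq_len(L)) B[[li + 1L]] <<- out[[li]]
    out
  }
  final_v <- function() V[[L]]
  list(step = step, final_v = final_v)
}

#' Batched forward simulation of a dense spiking network
#'
#' Vectorizes [run_network()] over samples for all-dense networks without
#' axonal delays (the crossbar-mapped topologies); results are identical
#' to the per-sample simulator. For a [submlp_ensemble()] the four
#' branches are simulated and their output counts summed
#' (`sum_outputs`) while the concatenated hidden counts are also returned.
#'
#' @param spec trained dense `network_spec` or `submlp_ensemble`.
#' @param X input array `(N, channels, ticks)`; for ensembles, a list of
#'   four such arrays.
#' @param extra_ticks silent ticks appended after the stimulus.
#' @param batch internal batch size (memory control).
#' @return list `(counts, hidden_counts, decisions, final_v,
#'   spike_totals)`; `spike_totals` is a per-population total over all
#'   samples (for ensembles, a list of four).
#' @export
snn_forward_batch <- function(spec, X, extra_ticks = 2L, batch = 128L) {
  if (!is_dense_nodelay(spec))
    stop("snn_forward_batch requires an all-dense, no-delay network")
  if (inherits(spec, "submlp_ensemble")) {
    runs <- lapply(seq_len(4L), function(k)
      snn_forward_batch(spec$branches[[k]], X[[k]], extra_ticks, batch))
    counts <- Reduce(`+`, lapply(runs, `[[`, "counts"))
    fv <- Reduce(`+`, lapply(runs, `[[`, "final_v"))
    return(list(counts = counts,
                hidden_counts = do.call(cbind,
                                        lapply(runs, `[[`, "hidden_counts")),
                decisions = decide_batch(counts, fv), final_v = fv,
                spike_totals = lapply(runs, `[[`, "spike_totals")))
  }
  N <- dim(X)[1]
  L <- length(spec$layers)
  K <- spec$layers[[L]]$units
  Hn <- if (L >= 2L) spec$layers[[L - 1L]]$units else dim(X)[2]
  counts <- matrix(0, N, K)
  hidden <- matrix(0, N, Hn)
  finalv <- matrix(0, N, K)
  totals <- setNames(numeric(L + 1L),
                     c("input", paste0("layer", seq_len(L))))
  T_ <- dim(X)[3]
  T_tot <- T_ + as.integer(extra_ticks)
  idx <- split(seq_len(N), ceiling(seq_len(N) / batch))
  for (b in idx) {
    Nb <- length(b)
    st <- make_stack(spec$layers, Nb)
    cb <- matrix(0, Nb, K)
    hb <- matrix(0, Nb, Hn)
    for (t in seq_len(T_tot)) {
      inp <- if (t <= T_) matrix(X[b, , t], Nb) else
        matrix(0, Nb, dim(X)[2])
      out <- st$step(inp)
      cb <- cb + out[[L]]
      hb <- hb + (if (L >= 2L) out[[L - 1L]] else inp)
      totals["input"] <- totals["input"] + sum(inp)
      for (li in seq_len(L))
        totals[li + 1L] <- totals[li + 1L] + sum(out[[li]])
    }
    counts[b, ] <- cb
    hidden[b, ] <- hb
    finalv[b, ] <- st$final_v()
  }
  list(counts = counts, hidden_counts = hidden,
       decisions = decide_batch(counts, finalv), final_v = finalv,
       spike_totals = totals)
}

decide_batch <- function(counts, final_v) {
  vapply(seq_len(nrow(counts)), function(i)
    decide(counts[i, ], final_v[i, ]), 0L)
}

# Batched fusion inference: simulate both trunks and the spiking head in
# lock-step without materializing per-tick hidden traces.
fusion_forward_batch <- function(fused, Xa, Xb, extra_ticks = 2L,
                                 batch = 128L) {
  trunk_layers <- function(net) {
    if (inherits(net, "submlp_ensemble"))
      lapply(net$branches, function(b) head(b$layers, -1L))
    else list(head(net$layers, -1L))
  }
  la <- trunk_layers(fused$net_a)
  lb <- trunk_layers(fused$net_b)
  Xa_l <- if (is.list(Xa) && !is.array(Xa)) Xa else list(Xa)
  Xb_l <- if (is.list(Xb) && !is.array(Xb)) Xb else list(Xb)
  N <- dim(Xa_l[[1]])[1]
  T_ <- dim(Xa_l[[1]])[3]
  T_tot <- T_ + as.integer(extra_ticks)
  K <- fused$head$units
  counts <- matrix(0, N, K)
  hidden <- matrix(0, N, fused$input_width)
  finalv <- matrix(0, N, K)
  for (b in split(seq_len(N), ceiling(seq_len(N) / batch))) {
    Nb <- length(b)
    sa <- lapply(la, make_stack, N = Nb)
    sb <- lapply(lb, make_stack, N = Nb)
    sh <- make_stack(list(fused$head), Nb)
    cb <- matrix(0, Nb, K)
    hb <- matrix(0, Nb, fused$input_width)
    for (t in seq_len(T_tot)) {
      hid <- vector("list", length(sa) + length(sb))
      for (j in seq_along(sa)) {
        inp <- if (t <= T_) matrix(Xa_l[[j]][b, , t], Nb)
               else matrix(0, Nb, dim(Xa_l[[j]])[2])
        o <- sa[[j]]$step(inp)
        hid[[j]] <- o[[length(o)]]
      }
      for (j in seq_along(sb)) {
        inp <- if (t <= T_) matrix(Xb_l[[j]][b, , t], Nb)
               else matrix(0, Nb, dim(Xb_l[[j]])[2])
        o <- sb[[j]]$step(inp)
        hid[[length(sa) + j]] <- o[[length(o)]]
      }
      hcat <- do.call(cbind, hid)
      cb <- cb + sh$step(hcat)[[1]]
      hb <- hb + hcat
    }
    counts[b, ] <- cb
    hidden[b, ] <- hb
    finalv[b, ] <- sh$final_v()
  }
  list(counts = counts, hidden_counts = hidden,
       decisions = decide_batch(counts, finalv), final_v = finalv)
}
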