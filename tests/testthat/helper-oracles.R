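# Independent reference implementations used as oracles. These are written
# scalar-first (one neuron, one synapse, one spike at a time) on purpose:
# they share no code path with the package's vectorized simulator.

# Naive event-driven simulation of an all-dense spiking network, same
# timing convention (1 tick transport latency + axonal delay).
oracle_run_dense <- function(spec, raster, extra_ticks = 0L) {
  counts_in <- raster$counts
  T_tot <- ncol(counts_in) + extra_ticks
  prev <- cbind(counts_in, matrix(0, nrow(counts_in), extra_ticks))
  final_v <- NULL
  totals <- c(input = sum(counts_in))
  for (li in seq_along(spec$layers)) {
    l <- spec$layers[[li]]
    out <- matrix(0, l$units, T_tot)
    ai <- (4096 - l$neuron$current_decay) / 4096
    av <- (4096 - l$neuron$voltage_decay) / 4096
    vend <- numeric(l$units)
    for (j in seq_len(l$units)) {
      iv <- 0
      vv <- 0
      for (t in seq_len(T_tot)) {
        a <- 0
        for (i in seq_len(nrow(l$weights))) {
          d <- if (is.null(l$delays)) 0L else l$delays[i, j]
          tc <- t - 1L - d
          if (tc >= 1L) a <- a + l$weights[i, j] * prev[i, tc]
        }
        iv <- iv * ai + a
        vv <- vv * av + iv
        if (vv >= l$neuron$threshold) {
          out[j, t] <- 1
          vv <- 0
        }
      }
      vend[j] <- vv
    }
    totals[paste0("layer", li)] <- sum(out)
    prev <- out
    final_v <- vend
  }
  counts <- rowSums(prev)
  list(counts = counts, trace = prev, final_v = final_v,
       spike_totals = totals)
}

# Brute-force per-spike SOP enumeration on a crossbar / direct-mapped core.
oracle_sops <- function(pre_spikes, fanouts, neurons_per_core, crossbar) {
  total <- 0
  useful <- 0
  for (p in seq_along(pre_spikes)) {
    n <- pre_spikes[p]
    while (n > 0) {                       # one spike at a time
      total <- total + if (crossbar) neurons_per_core else fanouts[p]
      useful <- useful + fanouts[p]
      n <- n - 1
    }
  }
  c(total = total, useful = useful)
}

# Plain-R delta-modulator tracking loop over the materialized interpolated
# signal (the package never materializes it).
oracle_delta_mod <- function(x, rate_hz, interp, delta) {
  n <- length(x)
  k <- seq(0, (n - 1) * interp)
  s <- approx(seq(0, n - 1) * interp, x, xout = k)$y
  t_us <- k * 1e6 / (rate_hz * interp)
  r <- s[1]
  up <- numeric(0)
  down <- numeric(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] - r >= delta - 1e-12) {
      up <- c(up, t_us[i])
      r <- r + delta
    } else if (r - s[i] >= delta - 1e-12) {
      down <- c(down, t_us[i])
      r <- r - delta
    }
  }
  list(up = up, down = down, interp_signal = s, interp_t_us = t_us)
}

# random small dense spiking network (<= 32 neurons)
random_dense_spec <- function(seed, n_in = 4L, layers = c(6L, 3L),
                              with_delays = FALSE, max_delay = 3L) {
  set.seed(seed)
  dims <- c(n_in, layers)
  ls <- lapply(seq_along(layers), function(li) {
    W <- matrix(round(rnorm(dims[li] * layers[li], sd = 1), 2),
                dims[li], layers[li])
    D <- if (with_delays)
      matrix(sample(0:max_delay, dims[li] * layers[li], TRUE),
             dims[li], layers[li])
    layer_dense(layers[li], weights = W, delays = D,
                neuron = neuron_config(
                  current_decay = sample(c(0, 512, 1024, 2048, 4096), 1),
                  voltage_decay = sample(c(0, 512, 1024, 4096), 1),
                  threshold = runif(1, 0.5, 2)),
                quant = quant_spec("float"))
  })
  network_spec(paste0("rand", seed), ls, input_shape = n_in)
}

random_raster <- function(seed, n_ch = 4L, ticks = 30L, p = 0.25) {
  set.seed(seed)
  spike_raster(matrix(rbinom(n_ch * ticks, 1L, p), n_ch, ticks))
}
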