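## Analytic cost model for crossbar neuromorphic processors: synaptic
## operation (SOP) accounting with dummy-operation overhead, the power
## decomposition P = P_leak + P_idle * f_clk + E_SOP * r_SOP, energy,
## processing time, energy-delay product and chip utilization.

#' Chip model
#'
#' @param name chip name.
#' @param neurons_per_core neurons per crossbar core.
#' @param n_cores number of cores.
#' @param e_sop_pj energy per synaptic operation in pJ.
#' @param f_clk_hz clock frequency in Hz.
#' @param cycles_per_sop clock cycles per SOP (2 on the modelled chips).
#' @param p_leak_mw,p_idle_mw_per_hz static power terms (default 0: the
#'   reported figures are dynamic power only).
#' @param crossbar TRUE if every spike entering a core addresses all its
#'   neurons (dummy-SOP overhead).
#' @export
chip_model <- function(name, neurons_per_core, n_cores, e_sop_pj, f_clk_hz,
                       cycles_per_sop = 2L, p_leak_mw = 0,
                       p_idle_mw_per_hz = 0, crossbar = TRUE) {
  if (!is.na(e_sop_pj) && e_sop_pj <= 0) stop("e_sop_pj must be > 0")
  structure(list(name = name, neurons_per_core = as.integer(neurons_per_core),
                 n_cores = as.integer(n_cores), e_sop_pj = e_sop_pj,
                 f_clk_hz = f_clk_hz, cycles_per_sop = as.integer(cycles_per_sop),
                 p_leak_mw = p_leak_mw, p_idle_mw_per_hz = p_idle_mw_per_hz,
                 crossbar = crossbar),
            class = "chip_model")
}

#' @describeIn chip_model ODIN preset: one 256-neuron crossbar core,
#'   8.4 pJ/SOP, 75 MHz at minimum supply voltage.
#' @export
chip_odin <- function() chip_model("odin", 256L, 1L, 8.4, 75e6)

#' @describeIn chip_model MorphIC preset: four 512-neuron crossbar cores,
#'   30 pJ/SOP, 55 MHz at minimum supply voltage.
#' @export
chip_morphic <- function() chip_model("morphic", 512L, 4L, 30, 55e6)

#' @describeIn chip_model Loihi placeholder: not a crossbar; energy and
#'   time are measured quantities, not predicted by this model.
#' @export
chip_loihi <- function() chip_model("loihi", 1024L, 128L, NA_real_, NA_real_,
                                    crossbar = FALSE)

## ---------------------------------------------------------------------------

dense_fanouts <- function(spec) {
  units <- vapply(spec$layers, function(l) {
    if (l$kind != "dense") stop("SOP accounting expects dense-only networks")
    l$units
  }, 0L)
  units
}

#' Count synaptic operations for one inference on a crossbar core
#'
#' On a crossbar core every spike entering the core triggers one SOP per
#' neuron in the core (`neurons_per_core` total), of which only the spikes'
#' actual fan-out are useful — e.g. on a 512-neuron core hosting a 210-unit
#' hidden layer and the 5 output units, each input spike costs 512 SOPs
#' (210 useful) and each hidden spike 512 SOPs (5 useful). On a
#' non-crossbar chip total = useful = spikes x fan-out.
#'
#' @param spec a dense `network_spec` or [submlp_ensemble()] mapped to the
#'   chip.
#' @param trace per-population spike totals for the inference: a named
#'   vector `c(input = , layer1 = , ..., layerL = )` as returned in
#'   `run_network()$spike_totals`; for an ensemble, a list of four such
#'   vectors (one per branch/core).
#' @param chip a [chip_model()].
#' @return list `(total, useful, per_core)`; `per_core` holds each core's
#'   total SOPs (processing time is set by the busiest core).
#' @export
count_sops <- function(spec, trace, chip) {
  if (is.null(chip) || !inherits(chip, "chip_model"))
    stop("network not mapped to a chip: pass a chip_model")
  if (inherits(spec, "submlp_ensemble")) {
    if (!is.list(trace) || length(trace) != 4L)
      stop("ensemble SOP accounting needs one trace per branch (4)")
    per <- lapply(seq_len(4L), function(k)
      count_sops(spec$branches[[k]], trace[[k]], chip))
    return(list(total = sum(vapply(per, `[[`, 0, "total")),
                useful = sum(vapply(per, `[[`, 0, "useful")),
                per_core = vapply(per, function(p) p$per_core[[1]], 0)))
  }
  fanouts <- dense_fanouts(spec)
  L <- length(fanouts)
  # presynaptic populations entering the core: the input plus every
  # non-final layer; the output layer's spikes leave the core.
  pre_spikes <- as.numeric(trace[c("input",
                                   if (L > 1L) paste0("layer", seq_len(L - 1L)))])
  if (anyNA(pre_spikes)) stop("trace must name input and layer1..layer", L - 1L)
  useful <- sum(pre_spikes * fanouts)
  total <- if (chip$crossbar) sum(pre_spikes) * chip$neurons_per_core
           else useful
  list(total = total, useful = useful, per_core = c(core1 = total))
}

#' Single-SOP accounting for fusion output-layer processing
#'
#' With an external mapping table, hidden-layer spikes are remapped to the
#' fusion output layer as single-SOP address events: each hidden spike
#' costs exactly one SOP per connected output neuron, with no crossbar
#' dummy overhead.
#'
#' @param n_hidden_spikes hidden-layer spikes entering the fusion head.
#' @param n_outputs output-layer width (default 5).
#' @return list `(total, useful)`, both `n_hidden_spikes * n_outputs`.
#' @export
fusion_sop_remap <- function(n_hidden_spikes, n_outputs = 5L) {
  s <- n_hidden_spikes * n_outputs
  list(total = s, useful = s)
}

#' Dynamic power of crossbar cores at a given SOP rate
#'
#' `P_dyn = E_SOP * r_SOP` summed over the active cores; the maximum
#' per-core rate is `f_clk / cycles_per_sop` (each SOP takes two clock
#' cycles).
#'
#' @param chip a [chip_model()].
#' @param r_sop per-core SOP processing rate in SOP/s.
#' @param n_cores_active number of active cores (default all).
#' @return dynamic power in mW.
#' @export
dynamic_power <- function(chip, r_sop, n_cores_active = chip$n_cores) {
  r_max <- chip$f_clk_hz / chip$cycles_per_sop
  if (r_sop > r_max)
    stop("r_sop ", r_sop, " exceeds the maximum per-core rate f_clk/",
         chip$cycles_per_sop, " = ", r_max)
  chip$e_sop_pj * 1e-12 * r_sop * n_cores_active * 1e3
}

#' Energy and processing time for one inference
#'
#' Cores run in parallel at the maximum SOP rate, so processing time is
#' `cycles_per_sop * max(per-core SOPs) / f_clk` and the dynamic energy is
#' `E_SOP * total SOPs`. At max rate `energy / time` equals the dynamic
#' power of the active cores.
#'
#' @param chip a [chip_model()].
#' @param sops_per_core numeric vector of per-core SOP totals.
#' @return list `(energy_uJ, time_ms)`.
#' @export
energy_and_time <- function(chip, sops_per_core) {
  list(energy_uJ = chip$e_sop_pj * 1e-12 * sum(sops_per_core) * 1e6,
       time_ms = chip$cycles_per_sop * max(sops_per_core, 0) /
         chip$f_clk_hz * 1e3)
}

#' Energy-delay product
#'
#' @param energy_uJ average energy per inference in uJ.
#' @param time_ms average inference time in ms.
#' @return EDP in uJ*s.
#' @export
edp <- function(energy_uJ, time_ms) energy_uJ * time_ms / 1000

#' Chip utilization of a mapped network
#'
#' Percentage of the chip's neuron resources taken by the hidden and
#' output layers: e.g. (230 + 5)/256 = 91.8% for the EMG MLP on ODIN,
#' 4 x (210 + 5)/2048 = 42.0% for the DVS subMLPs on MorphIC, and
#' 4 x 210/2048 = 41.0% for the MorphIC share of the fusion network
#' (whose output layer lives on ODIN).
#'
#' @param spec a `network_spec` or [submlp_ensemble()]; alternatively pass
#'   `n_neurons` directly.
#' @param chip a [chip_model()].
#' @param n_neurons optional explicit mapped-neuron count overriding the
#'   spec-derived count.
#' @return utilization in percent.
#' @export
utilization <- function(spec, chip, n_neurons = NULL) {
  if (is.null(n_neurons)) {
    n_neurons <- if (inherits(spec, "submlp_ensemble"))
      sum(vapply(spec$branches, function(b) sum(dense_fanouts(b)), 0))
    else sum(vapply(spec$layers, function(l)
      if (l$kind %in% c("dense", "conv")) prod(l$units %||% 0) else 0, 0))
  }
  100 * n_neurons / (chip$neurons_per_core * chip$n_cores)
}

#' Assemble a cost report for one inference
#'
#' Runs the full analytic chain: SOP accounting, per-core processing time,
#' dynamic energy, dynamic power at max rate, EDP and utilization.
#'
#' @param spec network spec mapped to `chip`.
#' @param trace spike trace (see [count_sops()]).
#' @param chip a [chip_model()].
#' @return object of class `cost_report`.
#' @export
cost_report <- function(spec, trace, chip) {
  s <- count_sops(spec, trace, chip)
  et <- energy_and_time(chip, s$per_core)
  n_active <- length(s$per_core)
  structure(list(chip = chip$name,
                 sop_total = s$total, sop_useful = s$useful,
                 dynamic_power_mW = dynamic_power(
                   chip, chip$f_clk_hz / chip$cycles_per_sop, n_active),
                 energy_uJ = et$energy_uJ,
                 processing_time_ms = et$time_ms,
                 edp_uJs = edp(et$energy_uJ, et$time_ms),
                 utilization_pct = utilization(spec, chip)),
            class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat(sprintf(paste0("<cost_report> %s: %s SOPs (%s useful), %.3g mW, ",
                     "%.3g uJ, %.3g ms, EDP %.3g uJ*s, util %.1f%%\n"),
              x$chip, format(x$sop_total), format(x$sop_useful),
              x$dynamic_power_mW, x$energy_uJ, x$processing_time_ms,
              x$edp_uJs, x$utilization_pct))
  invisible(x)
}
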